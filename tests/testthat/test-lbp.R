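test_that("constant images give all-equal LBP bits under the >= convention", {
  img <- matrix(0.37, 15, 15)
  fs <- extract_lbp(img, cbind(8, 8), scale_grid(c(3, 5, 7)), bits = 8)
  for (s in seq_along(fs$scales))
    expect_equal(as.integer(fs$desc[[s]]), rep(1L, 8))
})

test_that("LBP matches the per-neighbor comparison oracle", {
  # single bright central pixel at scale 3
  img <- matrix(0, 9, 9); img[5, 5] <- 1
  fs <- extract_lbp(img, cbind(5, 5), scale_grid(3), bits = 8)
  expect_equal(as.integer(fs$desc[[1]]), oracle_lbp(img, 5, 5, 3))
  expect_equal(as.integer(fs$desc[[1]]), rep(0L, 8))  # neighbors all darker
  # random images, random pixels and scales
  set.seed(11)
  for (rep in 1:50) {
    img <- matrix(runif(33 * 33), 33, 33)
    r <- sample(5:29, 1); c <- sample(5:29, 1); k <- sample(c(3, 5, 7), 1)
    fs <- extract_lbp(img, cbind(r, c), scale_grid(k))
    expect_equal(as.integer(fs$desc[[1]]), oracle_lbp(img, r, c, k),
                 tolerance = 0)
  }
})

test_that("LBP codes are invariant under constant intensity shift", {
  set.seed(7)
  for (rep in 1:10) {
    img <- matrix(runif(25 * 25), 25, 25)
    px <- cbind(sample(5:20, 8), sample(5:20, 8))
    a <- extract_lbp(img, px, scale_grid(c(3, 7)))
    b <- extract_lbp(img + 3.21, px, scale_grid(c(3, 7)))
    expect_identical(a$desc, b$desc)
  }
})

test_that("LBP validates its inputs", {
  img <- matrix(runif(100), 10, 10)
  expect_error(extract_lbp(img, cbind(11, 5), scale_grid(3)), "outside")
  expect_error(extract_lbp(img, cbind(5, 5), scale_grid(11)), "exceeds")
  expect_error(extract_lbp(img, cbind(5, 5), scale_grid(3), bits = 3),
               "bits")
  # descriptor length equals bits for every scale
  fs <- extract_lbp(img, cbind(5, 5), scale_grid(c(3, 5)), bits = 12)
  expect_true(all(vapply(fs$desc, ncol, 1L) == 12L))
})

test_that("rotation-invariant codes map rotations to one representative", {
  set.seed(3)
  img <- matrix(runif(21 * 21), 21, 21)
  fs <- extract_lbp(img, cbind(11, 11), scale_grid(5), rotation_invariant = TRUE)
  code <- as.integer(fs$desc[[1]])
  # the representative is lexicographically minimal among its own rotations
  rots <- sapply(0:7, function(s) code[(seq_len(8) + s - 1) %% 8 + 1])
  vals <- apply(rots, 2, function(b) sum(b * 2^(7:0)))  # bit 1 most significant
  expect_equal(sum(code * 2^(7:0)), min(vals))
})
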