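make_slice <- function(family, n, d_per_scale, seed) {
  set.seed(seed)
  make_msfs(family, lapply(d_per_scale, function(d) matrix(rnorm(n * d), n)))
}

test_that("uncapped pair enumeration is exhaustive", {
  pos <- make_slice("gabor", 2, c(3, 3), 1)
  neg <- make_slice("gabor", 1, c(3, 3), 2)
  k <- build_distance_kernels(pos, neg, pairs_per_slice = 100, seed = 1)
  expect_equal(ncol(k$H_p), 1L)  # choose(2, 2) within-positive pairs
  expect_equal(ncol(k$H_b), 2L)  # 2 x 1 positive-vs-negative pairs
})

test_that("S_p equals the explicit double sum over enumerated pairs", {
  pos <- make_slice("haralick", 5, c(2, 2, 2), 3)
  neg <- make_slice("haralick", 4, c(2, 2, 2), 4)
  k <- build_distance_kernels(pos, neg, pairs_per_slice = 1000, seed = 1)
  ref <- matrix(0, 3, 3)
  for (i in 1:4) for (j in (i + 1):5) {
    h <- vapply(1:3, function(s)
      sqrt(sum((pos$desc[[s]][i, ] - pos$desc[[s]][j, ])^2)), 1.0)
    ref <- ref + h %*% t(h)
  }
  expect_lt(max(abs(k$S_p - ref)), 1e-10)
  expect_equal(ncol(k$H_p), choose(5, 2))
})

test_that("identical positives give zero H_p but a well-defined R_p", {
  d <- lapply(1:2, function(s) matrix(1, 3, 4))  # 3 identical descriptors
  pos <- make_msfs("gabor", d)
  neg <- make_slice("gabor", 2, c(4, 4), 5)
  k <- build_distance_kernels(pos, neg, seed = 1)
  expect_true(all(k$H_p == 0))
  expect_true(all(k$S_p == 0))
  expect_true(all(is.finite(k$R_p)))
  expect_lt(max(abs(crossprod(k$R_p) - (k$S_p + diag(k$ridge, 2)))), 1e-8)
})

test_that("Cholesky factor reproduces the ridged intra-class kernel", {
  pos <- lapply(1:3, function(t) make_slice("phow", 6, c(8, 8), 10 + t))
  neg <- lapply(1:3, function(t) make_slice("phow", 5, c(8, 8), 20 + t))
  k <- build_distance_kernels(pos, neg, pairs_per_slice = 10, seed = 2)
  expect_lt(max(abs(crossprod(k$R_p) - (k$S_p + diag(k$ridge, 2)))), 1e-8)
  expect_true(all(k$H_p >= 0) && all(k$H_b >= 0))
  # per-slice caps respected and slices tagged
  expect_true(all(table(k$slice_p) <= 10))
  expect_true(all(table(k$slice_b) <= 10))
})

test_that("pair sampling is reproducible by seed", {
  pos <- lapply(1:2, function(t) make_slice("gabor", 30, c(3, 3), 30 + t))
  neg <- lapply(1:2, function(t) make_slice("gabor", 30, c(3, 3), 40 + t))
  k1 <- build_distance_kernels(pos, neg, pairs_per_slice = 50, seed = 9)
  k2 <- build_distance_kernels(pos, neg, pairs_per_slice = 50, seed = 9)
  k3 <- build_distance_kernels(pos, neg, pairs_per_slice = 50, seed = 10)
  expect_identical(k1$H_b, k2$H_b)
  expect_false(identical(k1$H_b, k3$H_b))
})

test_that("a within-positive pair must exist in some slice", {
  pos <- make_slice("gabor", 1, c(3, 3), 1)
  neg <- make_slice("gabor", 5, c(3, 3), 2)
  expect_error(build_distance_kernels(pos, neg, seed = 1), "positive")
})
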