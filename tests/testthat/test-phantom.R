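test_that("phantom generation is deterministic and bounded", {
  sp <- phantom_spec(seed = 42)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_true(all(a$image >= 0 & a$image <= 1))
  c <- generate_phantom(phantom_spec(seed = 43))
  expect_false(identical(a$image, c$image))
})

test_that("the lesion mask rasterizes the requested ellipse", {
  sp <- phantom_spec(height = 100, width = 100, center = c(50, 50),
                     axes = c(20, 12), seed = 1)
  ph <- generate_phantom(sp)
  area <- pi * 20 * 12
  perimeter <- pi * (3 * (20 + 12) - sqrt((3 * 20 + 12) * (20 + 3 * 12)))
  expect_lt(abs(sum(ph$mask) - area), perimeter + 1)  # within one pixel ring
  # mask is exactly the ellipse indicator
  rr <- matrix(1:100, 100, 100); cc <- t(rr)
  inside <- ((rr - 50) / 20)^2 + ((cc - 50) / 12)^2 <= 1
  expect_identical(ph$mask == 1, inside)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(height = 64, width = 64, center = c(5, 32),
                            axes = c(20, 10)), "bounds")
  expect_error(phantom_spec(planted_scale = 4), "odd")
  expect_error(phantom_spec(effect_size = -1))
})

test_that("a zero effect size makes the lesion texture match the background", {
  sp0 <- phantom_spec(effect_size = 0, seed = 7)
  ph <- generate_phantom(sp0)
  m <- ph$mask == 1
  # amplitude and mean statistics agree between classes
  expect_lt(abs(mean(ph$image[m]) - mean(ph$image[!m])), 0.02)
  expect_lt(abs(sd(ph$image[m]) - sd(ph$image[!m])), 0.02)
})

test_that("kernel fixtures are symmetric PSD with the planted gap", {
  k <- generate_kernel_fixture(4, 3, 5, 300, seed = 6)
  expect_equal(k$S_p, t(k$S_p))
  expect_equal(k$S_b, t(k$S_b))
  expect_true(all(eigen(k$S_p, only.values = TRUE)$values > -1e-8))
  expect_true(all(eigen(k$S_b, only.values = TRUE)$values > -1e-8))
  expect_true(all(k$H_p >= 0) && all(k$H_b >= 0))
  # between-class distances at the planted scale are ~gap x the others
  expect_gt(mean(k$H_b[3, ]), 3 * mean(k$H_b[-3, ]))
  expect_lt(abs(mean(k$H_p[3, ]) - mean(k$H_p[-3, ])), 0.1)
  expect_error(generate_kernel_fixture(3, 1, 5, n_pairs = 1), "n_pairs")
})

test_that("same-seed kernel fixtures are identical", {
  expect_identical(generate_kernel_fixture(3, 2, 5, 100, seed = 9),
                   generate_kernel_fixture(3, 2, 5, 100, seed = 9))
})
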