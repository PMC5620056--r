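test_that("update_a reproduces hand-evaluated closed forms", {
  # S_p = I, S_b = I, w = e1  ->  a = e1
  k <- make_kernels_from_gram(diag(3), diag(3))
  expect_equal(update_a(k, c(1, 0, 0)), c(1, 0, 0))
  # S_p = 4I (R_p = 2I), S_b = I, w = e1  ->  a = 0.5 e1
  k2 <- make_kernels_from_gram(4 * diag(3), diag(3))
  expect_equal(update_a(k2, c(1, 0, 0)), c(0.5, 0, 0))
})

test_that("update_a matches direct triangular-solve evaluation", {
  set.seed(17)
  for (rep in 1:100) {
    S <- sample(2:6, 1)
    A <- matrix(rnorm(S * S), S); S_p <- crossprod(A) + diag(S) * 0.1
    B <- matrix(rnorm(S * S), S); S_b <- crossprod(B)
    w <- abs(rnorm(S))
    k <- make_kernels_from_gram(S_p, S_b)
    ref <- solve(t(chol(S_p)), S_b %*% w) /
      sqrt(as.numeric(t(w) %*% S_b %*% S_b %*% w))
    expect_equal(update_a(k, w), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("update_a is scale-invariant in w and flags degenerate kernels", {
  set.seed(18)
  k <- generate_kernel_fixture(4, 1, 3, 50, seed = 2)
  w <- abs(rnorm(4))
  expect_equal(update_a(k, w), update_a(k, 7.3 * w), tolerance = 1e-12)
  kz <- make_kernels_from_gram(diag(3), diag(3))
  kz$S_b <- matrix(0, 3, 3)
  expect_error(update_a(kz, c(1, 1, 1)), class = "discrn_nondiscriminative")
})

test_that("solve_w handles the scalar problem in closed form", {
  # S = 1, eta = 0, alpha = 0: w = max(0, c / G)
  k <- make_kernels(matrix(2, 1, 1), matrix(3, 1, 1))  # S_p = 4, S_b = 9
  w <- solve_w(k, a = 1, alpha = 0, eta = 0)
  cvec <- as.numeric(k$S_b %*% backsolve(k$R_p, 1))    # = 4.5
  expect_equal(w, max(0, cvec / k$S_b[1, 1]), tolerance = 1e-12)
  expect_equal(w, 0.5, tolerance = 1e-12)
})

test_that("a large l1 penalty forces w to exactly zero", {
  set.seed(19)
  k <- generate_kernel_fixture(3, 2, 4, 100, seed = 3)
  a <- update_a(k, rep(1 / 3, 3))
  cvec <- as.numeric(k$S_b %*% backsolve(k$R_p, a))
  eta_big <- 2 * max(cvec) + 1  # gradient at 0 is -2c + eta > 0 everywhere
  expect_equal(solve_w(k, a, alpha = 0.1, eta = eta_big), rep(0, 3))
})

test_that("solve_w matches exhaustive active-set enumeration", {
  set.seed(20)
  for (rep in 1:40) {
    S <- sample(2:3, 1)
    k <- generate_kernel_fixture(S, sample(S, 1), runif(1, 1, 6),
                                 n_pairs = 40, seed = rep)
    a <- update_a(k, abs(rnorm(S)) + 0.1)
    alpha <- runif(1, 0, 0.5); eta <- runif(1, 0, 0.1)
    w <- solve_w(k, a, alpha, eta)
    G <- k$S_b + diag(alpha, S)
    cvec <- as.numeric(k$S_b %*% backsolve(k$R_p, a))
    ref <- oracle_snnls(G, cvec, eta)
    obj <- function(v) sum(v * (G %*% v)) - 2 * sum(cvec * v) + eta * sum(v)
    expect_true(all(w >= 0))
    expect_lt(obj(w) - ref$objective, 1e-6)
    # KKT residual: gradient >= 0, complementary slackness
    g <- 2 * (G %*% w - cvec) + eta
    expect_true(all(g > -1e-8 * max(1, abs(cvec))))
    expect_lt(max(abs(g[w > 0])), 1e-8 * max(1, max(abs(cvec)), max(diag(G))))
  }
})

test_that("sparsity is near-monotone in the l1 controller", {
  set.seed(23)
  worse <- 0
  for (rep in 1:100) {
    S <- 5
    k <- generate_kernel_fixture(S, sample(S, 1), 2, n_pairs = 60, seed = rep)
    a <- update_a(k, abs(rnorm(S)) + 0.1)
    scale <- max(abs(k$S_b))
    w1 <- solve_w(k, a, alpha = 0.1, eta = 1e-5 * scale)
    w2 <- solve_w(k, a, alpha = 0.1, eta = 1e-2 * scale)
    if (sum(w2 > 1e-12) > sum(w1 > 1e-12)) worse <- worse + 1
  }
  expect_lte(worse, 5)  # >= 95% of trials
})

test_that("alternation recovers a dominant scale and permutes with labels", {
  # S_b with mass only on scale 2, S_p = I
  S_b <- diag(c(0, 4, 0)); S_b[2, 2] <- 4
  k <- make_kernels_from_gram(diag(3), S_b)
  sw <- learn_scale_weights(k, alpha = 0.01, eta = 1e-4)
  expect_equal(sw$w, c(0, 1, 0), tolerance = 1e-8)
  # permuting scales permutes the weights identically
  perm <- c(3, 1, 2)
  k2 <- generate_kernel_fixture(3, 2, 5, 200, seed = 5)
  k3 <- k2
  k3$H_p <- k2$H_p[perm, ]; k3$H_b <- k2$H_b[perm, ]
  k3$S_p <- k3$H_p %*% t(k3$H_p); k3$S_b <- k3$H_b %*% t(k3$H_b)
  k3$R_p <- chol(k3$S_p + diag(k3$ridge, 3))
  sw2 <- learn_scale_weights(k2)
  sw3 <- learn_scale_weights(k3)
  expect_equal(sw3$w, sw2$w[perm], tolerance = 1e-6)
})

test_that("the w half-step never increases its subproblem objective", {
  set.seed(27)
  for (rep in 1:25) {
    S <- sample(2:6, 1)
    H_p <- matrix(abs(rnorm(S * 40)), S); H_b <- matrix(abs(rnorm(S * 40, 1)), S)
    k <- make_kernels(H_p, H_b, ridge = 1e-8 * sum(diag(H_p %*% t(H_p))) / S)
    w0 <- abs(rnorm(S)) + 0.1
    a <- update_a(k, w0)
    w1 <- solve_w(k, a, 0.1, 0.001)
    expect_lte(wstep_objective(k, a, w1, 0.1, 0.001),
               wstep_objective(k, a, w0, 0.1, 0.001) + 1e-9)
  }
})

test_that("the relaxed objective is non-increasing on planted fixtures", {
  for (s in 1:20) {
    sw <- learn_scale_weights(generate_kernel_fixture(4, 2, 3, 300, seed = s))
    o <- sw$objective
    if (length(o) > 1)
      expect_true(all(diff(o) <= 1e-9 * max(abs(o))))
  }
})

test_that("weights converge, are nonnegative and unit-norm", {
  for (s in 1:5) {
    sw <- learn_scale_weights(generate_kernel_fixture(5, 3, 4, 200, seed = s))
    expect_true(sw$converged)
    expect_true(all(sw$w >= 0))
    expect_equal(sum(sw$w^2), 1, tolerance = 1e-9)
  }
})

test_that("degenerate kernels fall back to uniform weights with a warning", {
  k <- make_kernels_from_gram(diag(3), diag(3))
  k$S_b <- matrix(0, 3, 3)
  k$H_b <- matrix(0, 3, 2)
  expect_warning(sw <- learn_scale_weights(k), "fallback")
  expect_true(sw$fallback)
  expect_equal(sw$w, rep(1 / sqrt(3), 3))
})

test_that("select_scales applies the sigma x w_max rule", {
  expect_equal(select_scales(c(0.5, 0.1, 0.4), sigma = 0.3), c(1L, 3L))
  # uniform weights: every scale selected for any sigma < 1
  expect_equal(select_scales(rep(0.2, 4), sigma = 0.99), 1:4)
  expect_error(select_scales(c(0, 0, 0)), "zero")
  expect_error(select_scales(c(1, 0), sigma = 1.2))
  # argmax always included; decreasing sigma never shrinks the set
  set.seed(29)
  for (rep in 1:20) {
    w <- abs(rnorm(6))
    s1 <- select_scales(w, sigma = 0.7)
    s2 <- select_scales(w, sigma = 0.3)
    expect_true(which.max(w) %in% s1)
    expect_true(all(s1 %in% s2))
  }
})

test_that("learned weights survive a JSON round trip", {
  sw <- learn_scale_weights(generate_kernel_fixture(3, 2, 5, 100, seed = 1))
  sw$family <- "gabor"; sw$scales <- scale_grid(c(3, 5, 7))
  path <- tempfile(fileext = ".json")
  write_scale_weights(sw, path)
  back <- read_scale_weights(path)
  expect_equal(back$w, sw$w, tolerance = 1e-12)
  expect_identical(back$selected, sw$selected)
  expect_equal(unclass(back$scales), c(3L, 5L, 7L), ignore_attr = TRUE)
})
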