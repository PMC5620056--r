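# Shared fixture builders for the test suite.

# assemble a distance_kernels object from explicit H_p / H_b (no ridge
# unless S_p is singular-ish, so hand-built identity kernels stay exact)
make_kernels <- function(H_p, H_b, ridge = 0) {
  S <- nrow(H_p)
  S_p <- H_p %*% t(H_p)
  S_b <- H_b %*% t(H_b)
  structure(
    list(H_p = H_p, H_b = H_b, S_p = S_p, S_b = S_b,
         R_p = chol(S_p + diag(ridge, S)), ridge = ridge,
         slice_p = rep(1L, ncol(H_p)), slice_b = rep(1L, ncol(H_b)),
         family = "test", scales = seq_len(S)),
    class = "distance_kernels"
  )
}

# kernels object with prescribed S_p / S_b Gram matrices (H matrices are
# PSD square roots so that every derived quantity stays consistent)
make_kernels_from_gram <- function(S_p, S_b) {
  psd_sqrt <- function(M) {
    e <- eigen(M, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(M))
  }
  structure(
    list(H_p = psd_sqrt(S_p), H_b = psd_sqrt(S_b), S_p = S_p, S_b = S_b,
         R_p = chol(S_p), ridge = 0,
         slice_p = rep(1L, nrow(S_p)), slice_b = rep(1L, nrow(S_b)),
         family = "test", scales = seq_len(nrow(S_p))),
    class = "distance_kernels"
  )
}

# minimal feature-set constructor for distance / kernel tests
make_msfs <- function(family, desc_per_scale, coords = NULL) {
  n <- nrow(desc_per_scale[[1]])
  if (is.null(coords)) coords <- cbind(row = seq_len(n), col = seq_len(n))
  structure(
    list(family = family, scales = scale_grid(2 * seq_along(desc_per_scale) + 1),
         coords = coords, desc = desc_per_scale),
    class = "multiscale_features"
  )
}

# small textured training pair for classifier tests: two classes separated
# linearly in feature space
separable_features <- function(n = 60, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n * p), 2 * n, p)
  X[seq_len(n), 1] <- X[seq_len(n), 1] + 6
  list(X = X, y = rep(c(1L, 0L), each = n))
}

# quick phantom pair (smaller than the full verification-size phantoms)
small_phantoms <- function(seeds, size = 64L, effect = 1.5) {
  lapply(seeds, function(s)
    generate_phantom(phantom_spec(height = size, width = size,
                                  effect_size = effect, seed = s)))
}
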