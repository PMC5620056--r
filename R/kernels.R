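#' Intra- and inter-class distance kernels
#'
#' Builds the per-scale distance kernels that drive scale learning. For each
#' slice, up to `pairs_per_slice` within-positive pairs and up to
#' `pairs_per_slice` positive-vs-negative pairs are sampled (uniformly,
#' without replacement, reproducibly by `seed`); the per-scale distance
#' vectors of the sampled pairs form the columns of `H_p` (`S x N_p`) and
#' `H_b` (`S x N_b`). The Gram matrices `S_p = H_p %*% t(H_p)` (intra-class)
#' and `S_b = H_b %*% t(H_b)` (inter-class) summarize them, and `R_p` is the
#' upper-triangular Cholesky factor with `t(R_p) %*% R_p = S_p + ridge * I`.
#' A small ridge (`1e-8 * mean(diag(S_p))`, with an absolute floor for the
#' all-zero case) keeps the factorization defined when `S_p` is singular.
#'
#' @param pos,neg `multiscale_features` objects, or lists of them (one per
#'   slice); positives and negatives of slice `t` are `pos[[t]]`, `neg[[t]]`.
#' @param pairs_per_slice cap on sampled pairs per slice and kind; 2000 by
#'   default.
#' @param seed integer seed for pair sampling.
#' @param metric optional distance metric override (see
#'   [pairwise_scale_distances()]).
#' @return an object of class `distance_kernels` with elements `H_p`, `H_b`,
#'   `S_p`, `S_b`, `R_p`, `ridge`, `slice_p`, `slice_b`, `family`, `scales`.
#' @export
build_distance_kernels <- function(pos, neg, pairs_per_slice = 2000L,
                                   seed = 1L, metric = NULL) {
  if (inherits(pos, "multiscale_features")) pos <- list(pos)
  if (inherits(neg, "multiscale_features")) neg <- list(neg)
  if (length(pos) != length(neg))
    stop("pos and neg must have the same number of slices")
  if (length(pos) == 0L) stop("no slices given")
  if (pairs_per_slice < 1L) stop("pairs_per_slice must be >= 1")
  n_pos <- vapply(pos, function(f) nrow(f$coords), 1L)
  n_neg <- vapply(neg, function(f) nrow(f$coords), 1L)
  if (all(n_pos < 2L))
    stop("no slice has >= 2 positive samples; no within-positive pair exists")
  family <- pos[[1L]]$family
  scales <- pos[[1L]]$scales

  Hp_cols <- list(); Hb_cols <- list()
  slice_p <- integer(0); slice_b <- integer(0)
  with_seed(seed, {
    for (t in seq_along(pos)) {
      np <- n_pos[t]; nn <- n_neg[t]
      if (np >= 2L) {
        all_pp <- utils::combn(np, 2L)           # 2 x choose(np, 2)
        keep <- if (ncol(all_pp) > pairs_per_slice)
          sample.int(ncol(all_pp), pairs_per_slice) else seq_len(ncol(all_pp))
        pp <- t(all_pp[, keep, drop = FALSE])
        Hp_cols[[length(Hp_cols) + 1L]] <-
          pairwise_scale_distances(pos[[t]], pos[[t]], pairs = pp,
                                   metric = metric)
        slice_p <- c(slice_p, rep(t, nrow(pp)))
      }
      if (np >= 1L && nn >= 1L) {
        ntot <- np * nn
        keep <- if (ntot > pairs_per_slice)
          sample.int(ntot, pairs_per_slice) else seq_len(ntot)
        pb <- cbind((keep - 1L) %% np + 1L, (keep - 1L) %/% np + 1L)
        Hb_cols[[length(Hb_cols) + 1L]] <-
          pairwise_scale_distances(pos[[t]], neg[[t]], pairs = pb,
                                   metric = metric)
        slice_b <- c(slice_b, rep(t, nrow(pb)))
      }
    }
  })
  H_p <- do.call(cbind, Hp_cols)
  H_b <- do.call(cbind, Hb_cols)
  if (is.null(H_b) || ncol(H_b) == 0L)
    stop("no positive-vs-negative pair could be formed")
  S <- length(scales)
  S_p <- H_p %*% t(H_p)
  S_b <- H_b %*% t(H_b)
  ridge <- 1e-8 * sum(diag(S_p)) / S
  if (ridge <= 0) ridge <- 1e-8
  R_p <- chol(S_p + diag(ridge, S))
  structure(
    list(H_p = H_p, H_b = H_b, S_p = S_p, S_b = S_b, R_p = R_p,
         ridge = ridge, slice_p = slice_p, slice_b = slice_b,
         family = family, scales = scales),
    class = "distance_kernels"
  )
}

#' @export
print.distance_kernels <- function(x, ...) {
  cat(sprintf(
    "distance_kernels: family=%s, S=%d scales, N_p=%d, N_b=%d pairs\n",
    x$family, nrow(x$H_p), ncol(x$H_p), ncol(x$H_b)
  ))
  invisible(x)
}
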