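#' Per-scale distance vectors between two feature sets
#'
#' For each requested pair of samples (one from `A`, one from `B`) the
#' per-scale basic distance is stacked into a column vector `h` of length
#' `S`: the Hamming distance between bit vectors for LBP, the Euclidean
#' distance otherwise. The weighted dissimilarity between two multi-scale
#' descriptors is then `sum(w * h)` for a scale weight vector `w`.
#'
#' @param A,B `multiscale_features` objects sharing family and scale grid.
#' @param pairs two-column integer matrix of (index into A, index into B)
#'   pairs; by default all `nA * nB` combinations.
#' @param metric `"hamming"` or `"euclidean"`; defaults to the family's
#'   canonical metric.
#' @return an `S x npairs` matrix whose columns are the vectors `h`.
#' @export
pairwise_scale_distances <- function(A, B, pairs = NULL, metric = NULL) {
  stopifnot(inherits(A, "multiscale_features"),
            inherits(B, "multiscale_features"))
  if (!identical(A$family, B$family))
    stop("feature sets have different families")
  if (!identical(unclass(A$scales), unclass(B$scales)))
    stop("feature sets have different scale grids")
  if (is.null(metric)) metric <- family_metric(A$family)
  metric <- match.arg(metric, c("hamming", "euclidean"))
  nA <- nrow(A$coords); nB <- nrow(B$coords)
  if (is.null(pairs))
    pairs <- cbind(rep(seq_len(nA), times = nB),
                   rep(seq_len(nB), each = nA))
  pairs <- as.matrix(pairs)
  S <- length(A$scales)
  h <- matrix(0, S, nrow(pairs))
  for (s in seq_len(S)) {
    d <- A$desc[[s]][pairs[, 1L], , drop = FALSE] -
         B$desc[[s]][pairs[, 2L], , drop = FALSE]
    h[s, ] <- if (metric == "hamming") rowSums(abs(d))
              else sqrt(rowSums(d * d))
  }
  h
}
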