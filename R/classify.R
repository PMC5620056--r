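#' Train the pixel classifier
#'
#' Fits a Random Forest to the (balanced) training descriptors; predictions
#' are per-pixel class probabilities. The pipeline default is 50 trees.
#'
#' @param features numeric matrix, one row per training pixel (concatenated
#'   selected-scale descriptors of all feature families).
#' @param labels binary vector (0/1 or logical), one per row.
#' @param n_trees number of trees; 50 by default.
#' @param seed integer seed for the forest's bootstrap sampling.
#' @return a fitted `randomForest` classifier.
#' @export
train_classifier <- function(features, labels, n_trees = 50L, seed = 1L) {
  features <- as.matrix(features)
  y <- factor(as.integer(labels != 0), levels = c(0L, 1L))
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (nrow(features) != length(y))
    stop("feature rows and labels differ in length")
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  with_seed(seed,
    randomForest::randomForest(x = features, y = y, ntree = n_trees))
}

# Per-pixel lesion probability from a fitted forest.
predict_proba <- function(rf, features) {
  features <- as.matrix(features)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  as.numeric(predict(rf, features, type = "prob")[, "1"])
}

new_heatmap <- function(probs, quantized = FALSE) {
  structure(list(probs = probs, quantized = quantized),
            class = "probability_heatmap")
}

#' @export
print.probability_heatmap <- function(x, ...) {
  cat(sprintf("probability_heatmap: %dx%d, %s, range [%.3f, %.3f]\n",
              nrow(x$probs), ncol(x$probs),
              if (x$quantized) "quantized" else "raw",
              min(x$probs), max(x$probs)))
  invisible(x)
}

#' Majority-vote heatmap smoothing over superpixels
#'
#' Pixel probabilities are first quantized to the eleven levels
#' `{0, 0.1, ..., 1}` (rounding half up); within each superpixel every pixel
#' is then set to the modal level, ties broken toward the smaller level.
#' The operation is idempotent and conserves the level set.
#'
#' @param hm a `probability_heatmap` (or plain numeric matrix in `[0, 1]`).
#' @param spx a [segment_superpixels()] map of the same shape.
#' @return a quantized `probability_heatmap`, constant within superpixels.
#' @export
smooth_heatmap <- function(hm, spx) {
  probs <- if (inherits(hm, "probability_heatmap")) hm$probs else hm
  stopifnot(inherits(spx, "superpixel_map"),
            all(dim(probs) == dim(spx$labels)))
  lev <- pmin(pmax(as.integer(floor(probs * 10 + 0.5)), 0L), 10L)  # 0..10
  lab <- as.vector(spx$labels)
  counts <- matrix(tabulate((lab - 1L) * 11L + as.vector(lev) + 1L,
                            nbins = spx$n * 11L),
                   nrow = spx$n, ncol = 11L, byrow = TRUE)
  modal <- max.col(counts, ties.method = "first") - 1L  # smaller level wins
  out <- matrix(modal[lab] / 10, nrow(probs), ncol(probs))
  new_heatmap(out, quantized = TRUE)
}

#' Rank-based AUC of a heatmap against a lesion mask
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney
#' statistic over all pixels, with midranks for ties: 1 for perfect ranking,
#' 0.5 for chance.
#'
#' @param hm a `probability_heatmap` or numeric score matrix.
#' @param mask binary matrix (nonzero = lesion); must contain both classes.
#' @param roi optional logical matrix restricting the evaluation domain
#'   (e.g. an organ region, or [interior_roi()] to exclude pixels whose
#'   feature windows cross the image border); `NULL` evaluates every pixel.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(hm, mask, roi = NULL) {
  scores <- if (inherits(hm, "probability_heatmap")) hm$probs else hm
  keep <- if (is.null(roi)) rep(TRUE, length(scores)) else as.vector(roi != 0)
  pos <- as.vector(mask != 0)[keep]
  if (!any(pos) || all(pos)) stop("mask must contain both classes")
  r <- rank(as.vector(scores)[keep], ties.method = "average")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Interior region of interest for border-safe evaluation
#'
#' Pixels near the image border are described by feature windows that
#' partly cover reflect-padded (extrapolated) content; their descriptors
#' are systematically atypical, which biases whole-image rank statistics.
#' This helper returns the logical mask of pixels whose windows are fully
#' supported by real image content under a given configuration, for use as
#' the `roi` of [evaluate_auc()].
#'
#' @param dim image dimensions `c(rows, cols)` (or a matrix to take them
#'   from).
#' @param config a [discrn_config()]; the margin is the largest padding any
#'   enabled family needs at the largest scale.
#' @return logical matrix, `TRUE` on the interior.
#' @export
interior_roi <- function(dim, config = discrn_config()) {
  if (is.matrix(dim)) dim <- base::dim(dim)
  kmax <- max(unclass(config$scales))
  r <- (kmax - 1L) %/% 2L
  margin <- 0L
  for (fam in config$families)
    margin <- max(margin, switch(fam,
      lbp = r + 1L,
      gabor = r,
      haralick = r,
      phow = 2L * as.integer(ceiling(kmax / 4)) + 1L))
  roi <- matrix(FALSE, dim[1], dim[2])
  if (dim[1] > 2 * margin && dim[2] > 2 * margin)
    roi[(margin + 1L):(dim[1] - margin), (margin + 1L):(dim[2] - margin)] <- TRUE
  roi
}
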