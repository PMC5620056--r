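#' Superpixel-balanced training-set sampling
#'
#' Builds a balanced pixel training set from a binary lesion mask: (1) all
#' lesion (positive) pixels are included; (2) one representative pixel per
#' fully-negative superpixel -- the member pixel closest to the region
#' centroid -- seeds the negative class; (3) if the centers alone exceed the
#' positive count, a seeded subsample of centers is used, otherwise further
#' negative pixels are sampled uniformly (seeded, without replacement) until
#' the class counts match.
#'
#' @param mask binary matrix (nonzero = lesion).
#' @param spx a [segment_superpixels()] map of the same image.
#' @param seed integer seed controlling all sampling.
#' @return an object of class `training_samples` with equal-size coordinate
#'   matrices `positive` and `negative` (1-based row, col).
#' @export
sample_balanced_training <- function(mask, spx, seed = 1L) {
  stopifnot(inherits(spx, "superpixel_map"))
  mask <- mask != 0
  if (!any(mask)) stop("mask has no positive pixel")
  if (all(mask)) stop("mask has no negative pixel")
  if (!all(dim(mask) == dim(spx$labels)))
    stop("mask and superpixel map have different shapes")
  pos <- which(mask, arr.ind = TRUE)
  colnames(pos) <- c("row", "col")
  n_pos <- nrow(pos)

  centers <- superpixel_centers(spx)
  # fully-negative superpixels only
  frac_pos <- tapply(as.vector(mask), as.vector(spx$labels), mean)
  neg_regions <- which(frac_pos == 0)
  centers <- centers[spx$labels[centers] %in% neg_regions, , drop = FALSE]

  neg <- with_seed(seed, {
    if (nrow(centers) >= n_pos) {
      centers[sample.int(nrow(centers), n_pos), , drop = FALSE]
    } else {
      taken <- matrix(FALSE, nrow(mask), ncol(mask))
      taken[centers] <- TRUE
      pool <- which(!mask & !taken, arr.ind = TRUE)
      need <- n_pos - nrow(centers)
      if (need > nrow(pool))
        stop("not enough negative pixels to balance the classes")
      extra <- pool[sample.int(nrow(pool), need), , drop = FALSE]
      colnames(extra) <- c("row", "col")
      rbind(centers, extra)
    }
  })
  colnames(neg) <- c("row", "col")
  structure(list(positive = pos, negative = neg, seed = seed),
            class = "training_samples")
}

#' @export
print.training_samples <- function(x, ...) {
  cat(sprintf("training_samples: %d positive, %d negative pixels\n",
              nrow(x$positive), nrow(x$negative)))
  invisible(x)
}
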