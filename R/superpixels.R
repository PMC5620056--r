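#' SLIC superpixel segmentation
#'
#' Spatially regularized k-means on (intensity, row, col). Cluster centers
#' start on a grid with step `rSize`; the spatial term is weighted by
#' `reqStr / rSize^2` so that `reqStr` is comparable across superpixel
#' sizes. Intensities are rescaled to `[0, 1]` before clustering so that
#' `reqStr` has a fixed meaning regardless of the image's dynamic range. A
#' final connected-components pass guarantees that every returned region is
#' 4-connected; regions smaller than `rSize^2 / 4` are absorbed into an
#' adjacent region. An image smaller than `rSize` in either dimension yields
#' a single-region map.
#'
#' @param image numeric matrix (grayscale image).
#' @param rSize nominal superpixel side in pixels (>= 2); 8 by default.
#' @param reqStr spatial regularization strength; 0.01 by default.
#' @param iters number of k-means iterations; 10 by default.
#' @return an object of class `superpixel_map`: `labels` (integer matrix,
#'   labels 1..n), `n`, `rSize`, `reqStr`.
#' @export
segment_superpixels <- function(image, rSize = 8L, reqStr = 0.01,
                                iters = 10L) {
  stopifnot(is.matrix(image), rSize >= 2L)
  rng <- range(image)
  img01 <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
           else image * 0
  labels <- cpp_slic(img01, as.integer(rSize), reqStr, as.integer(iters))
  structure(
    list(labels = labels, n = max(labels), rSize = as.integer(rSize),
         reqStr = reqStr),
    class = "superpixel_map"
  )
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("superpixel_map: %d regions (%dx%d, rSize=%d, reqStr=%g)\n",
              x$n, nrow(x$labels), ncol(x$labels), x$rSize, x$reqStr))
  invisible(x)
}

# Center pixel of every superpixel: the member pixel closest to the region
# centroid (so the center always lies inside the region).
superpixel_centers <- function(spx) {
  lab <- as.vector(spx$labels)
  H <- nrow(spx$labels)
  rows <- rep(seq_len(H), times = ncol(spx$labels))
  cols <- rep(seq_len(ncol(spx$labels)), each = H)
  cr <- tapply(rows, lab, mean)
  cc <- tapply(cols, lab, mean)
  d2 <- (rows - cr[lab])^2 + (cols - cc[lab])^2
  ord <- order(lab, d2)
  first <- ord[!duplicated(lab[ord])]
  cbind(row = rows[first], col = cols[first])
}
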