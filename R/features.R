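#' @name multiscale-features
#' @title Multi-scale texture feature sets
#'
#' @description
#' Each extractor computes one fixed-length descriptor per sampled pixel per
#' scale and returns a `multiscale_features` object holding, for every scale
#' in the grid, an `n x d` descriptor matrix. Descriptor lengths per family:
#' LBP `bits` (8 by default, as a 0/1 bit vector), Gabor one response
#' magnitude per angle, Haralick 14 co-occurrence statistics, PHOW 128.
#'
#' Images are numeric matrices in R orientation (`image[row, col]`); pixel
#' coordinates are 1-based `(row, col)` pairs. Before extraction the image is
#' reflect-padded by the largest radius the family needs at the largest
#' scale, identically at train and test time, so border pixels are valid
#' sample locations.
#' @param image numeric matrix (grayscale image).
#' @param pixels two-column matrix of 1-based (row, col) coordinates.
#' @param scales a [scale_grid()] (or vector coercible to one).
#' @return a `multiscale_features` object.
NULL

FAMILIES <- c("lbp", "gabor", "haralick", "phow")

# Distance metric per family: LBP bit vectors use Hamming distance, all
# real-valued families use Euclidean distance.
family_metric <- function(family) {
  switch(match.arg(family, FAMILIES), lbp = "hamming", "euclidean")
}

new_msfs <- function(family, scales, coords, desc) {
  structure(
    list(family = family, scales = scales, coords = coords, desc = desc),
    class = "multiscale_features"
  )
}

#' @export
print.multiscale_features <- function(x, ...) {
  cat(sprintf(
    "multiscale_features: family=%s, %d pixels, scales %s, dim %s\n",
    x$family, nrow(x$coords),
    paste(unclass(x$scales), collapse = "/"),
    paste(vapply(x$desc, ncol, 1L), collapse = "/")
  ))
  invisible(x)
}

# Reflect padding (mirror about the edge pixel, edge not duplicated),
# requires pad <= dim - 1.
pad_reflect <- function(image, pad) {
  if (pad == 0L) return(image)
  h <- nrow(image); w <- ncol(image)
  if (pad > h - 1L || pad > w - 1L)
    stop("window scale too large for image size")
  ridx <- c((pad + 1L):2L, 1L:h, (h - 1L):(h - pad))
  cidx <- c((pad + 1L):2L, 1L:w, (w - 1L):(w - pad))
  image[ridx, cidx, drop = FALSE]
}

check_pixels <- function(image, pixels) {
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 2L) stop("pixels must be a two-column (row, col) matrix")
  storage.mode(pixels) <- "integer"
  if (any(pixels[, 1L] < 1L) || any(pixels[, 1L] > nrow(image)) ||
      any(pixels[, 2L] < 1L) || any(pixels[, 2L] > ncol(image)))
    stop("pixel coordinates outside the image")
  pixels
}

check_scales <- function(image, scales) {
  scales <- as_scale_grid(scales)
  if (max(scales) > min(nrow(image), ncol(image)))
    stop("largest window scale exceeds the image side")
  scales
}

#' Multi-scale local binary patterns
#'
#' For a window of side `k`, `bits` neighbors are sampled (with bilinear
#' interpolation) equally spaced on a circle of radius `(k - 1) / 2`; bit j
#' is 1 when the neighbor intensity is greater than or equal to the center
#' intensity (ties map to 1; the comparison tolerates 1e-12 relative
#' rounding so interpolation noise cannot flip an exact tie). Circle offsets
#' within 1e-9 of an integer are snapped to it, so axis-aligned samples read
#' pixels exactly. Codes are invariant under adding a constant to
#' all intensities. The descriptor is the raw 0/1 bit vector so that the
#' Hamming distance between two codes is a plain vector difference.
#'
#' @inheritParams multiscale-features
#' @param bits number of circle samples (code length), >= 4; 8 by default.
#' @param rotation_invariant map each code to its minimal circular rotation.
#' @export
extract_lbp <- function(image, pixels, scales, bits = 8L,
                        rotation_invariant = FALSE) {
  scales <- check_scales(image, scales)
  pixels <- check_pixels(image, pixels)
  bits <- as.integer(bits)
  if (bits < 4L) stop("bits must be >= 4")
  pad <- as.integer((max(scales) - 1L) / 2L) + 1L  # +1 for bilinear support
  padded <- pad_reflect(image, pad)
  desc <- lapply(as.integer(scales), function(k) {
    r <- (k - 1) / 2
    cpp_lbp(padded, pixels[, 1L] + pad, pixels[, 2L] + pad, r, bits,
            rotation_invariant)
  })
  names(desc) <- as.character(unclass(scales))
  new_msfs("lbp", scales, pixels, desc)
}

# Complex Gabor kernel of side k: carrier wavelength lambda = k, Gaussian
# envelope sd = 0.5 * lambda, orientation theta in degrees measured from the
# column (x) axis. The kernel is DC-corrected (complex mean subtracted) so a
# constant image gives exactly zero response.
gabor_kernel <- function(k, theta_deg) {
  r <- (k - 1) / 2
  off <- seq(-r, r)
  dr <- matrix(off, k, k)          # row offsets vary down the rows
  dc <- matrix(off, k, k, byrow = TRUE)
  th <- theta_deg * pi / 180
  lambda <- k
  sigma <- 0.5 * lambda
  env <- exp(-(dr^2 + dc^2) / (2 * sigma^2))
  phase <- 2 * pi * (dc * cos(th) + dr * sin(th)) / lambda
  kern <- env * exp(1i * phase)
  kern - mean(kern)
}

#' Multi-scale Gabor filter-bank responses
#'
#' For each scale `k` a complex Gabor kernel of side `k` (wavelength `k`,
#' Gaussian envelope sd `k / 2`, DC-corrected) is correlated with the window
#' around each pixel at each orientation; the descriptor entry is the
#' response magnitude, so the descriptor length equals the number of angles.
#'
#' @inheritParams multiscale-features
#' @param angles orientations in degrees; `c(0, 90, 180)` by default.
#' @export
extract_gabor <- function(image, pixels, scales, angles = c(0, 90, 180)) {
  scales <- check_scales(image, scales)
  pixels <- check_pixels(image, pixels)
  if (length(angles) == 0L) stop("angles must be non-empty")
  pad <- as.integer((max(scales) - 1L) / 2L)
  padded <- pad_reflect(image, pad)
  desc <- lapply(as.integer(scales), function(k) {
    resp <- vapply(angles, function(th) {
      kern <- gabor_kernel(k, th)
      cpp_kernel_response(padded, pixels[, 1L] + pad, pixels[, 2L] + pad,
                          Re(kern), Im(kern))
    }, numeric(nrow(pixels)))
    matrix(resp, nrow = nrow(pixels))
  })
  names(desc) <- as.character(unclass(scales))
  new_msfs("gabor", scales, pixels, desc)
}

#' Multi-scale Haralick co-occurrence statistics
#'
#' Window intensities are quantized to `gray_levels` levels over the window
#' range; the gray-level co-occurrence matrix is accumulated over the four
#' distance-1 offsets (0, 45, 90, 135 degrees), symmetrized and normalized;
#' the 14 classic statistics are computed on the pooled matrix. Degenerate
#' single-level windows give 0 for correlation-type statistics, never NaN;
#' the 14th statistic (maximal correlation coefficient) falls back to 0
#' whenever undefined.
#'
#' @inheritParams multiscale-features
#' @param gray_levels number of quantization levels (>= 2), 32 by default.
#' @export
extract_haralick <- function(image, pixels, scales, gray_levels = 32L) {
  scales <- check_scales(image, scales)
  pixels <- check_pixels(image, pixels)
  gray_levels <- as.integer(gray_levels)
  if (gray_levels < 2L) stop("gray_levels must be >= 2")
  pad <- as.integer((max(scales) - 1L) / 2L)
  padded <- pad_reflect(image, pad)
  desc <- lapply(as.integer(scales), function(k) {
    cpp_haralick(padded, pixels[, 1L] + pad, pixels[, 2L] + pad, k,
                 gray_levels)
  })
  names(desc) <- as.character(unclass(scales))
  new_msfs("haralick", scales, pixels, desc)
}

#' Multi-scale dense-SIFT (PHOW) descriptors
#'
#' Scale `k` maps to a SIFT spatial bin of side `ceiling(k / 4)` pixels; the
#' descriptor is the classic 4x4 spatial by 8 orientation histogram of
#' gradient magnitudes (128 values), L2-normalized with the usual 0.2
#' clipping. Flat patches (gradient norm below 1e-10) yield all-zero
#' descriptors.
#'
#' @inheritParams multiscale-features
#' @export
extract_phow <- function(image, pixels, scales) {
  scales <- check_scales(image, scales)
  pixels <- check_pixels(image, pixels)
  binsz <- as.integer(ceiling(as.integer(scales) / 4))
  pad <- max(2L * binsz + 1L)
  padded <- pad_reflect(image, pad)
  desc <- lapply(binsz, function(b) {
    cpp_dense_sift(padded, pixels[, 1L] + pad, pixels[, 2L] + pad, b)
  })
  names(desc) <- as.character(unclass(scales))
  new_msfs("phow", scales, pixels, desc)
}

# Dispatch an extractor by family name using the parameters in `config`
# (see discrn_config()).
extract_family <- function(image, pixels, family, scales, config) {
  switch(match.arg(family, FAMILIES),
    lbp = extract_lbp(image, pixels, scales, bits = config$bits,
                      rotation_invariant = config$rotation_invariant),
    gabor = extract_gabor(image, pixels, scales, angles = config$angles),
    haralick = extract_haralick(image, pixels, scales,
                                gray_levels = config$gray_levels),
    phow = extract_phow(image, pixels, scales)
  )
}

#' Convert an RGB array to grayscale by luminance
#'
#' Uses the Rec. 601 luma weights `0.299 R + 0.587 G + 0.114 B`. Grayscale
#' matrices pass through unchanged.
#'
#' @param image numeric matrix, or `H x W x 3` (or deeper) array.
#' @return a numeric matrix.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3L && dim(image)[3L] >= 3L)
    return(0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L])
  if (length(dim(image)) == 3L && dim(image)[3L] %in% c(1L, 2L))
    return(image[, , 1L])
  stop("unsupported image array shape")
}
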