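#' Scale grid of square window sizes
#'
#' A scale grid is the ordered list of odd window side-lengths (in pixels) at
#' which every texture family is extracted. Typical grids are `c(3, 5, 7)`
#' for low-resolution radiology and up to nine scales
#' (`c(3, 5, 7, 9, 11, 13, 15, 19, 25)`) for high-resolution histology.
#'
#' @param sizes integer vector of odd window side-lengths, strictly
#'   increasing, each >= 3.
#' @return an integer vector of class `"scale_grid"`.
#' @examples
#' scale_grid(c(3, 5, 7))
#' @export
scale_grid <- function(sizes) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || anyNA(sizes))
    stop("scale grid must contain at least one window size")
  if (any(sizes < 3L)) stop("window sizes must be >= 3")
  if (any(sizes %% 2L == 0L)) stop("window sizes must be odd")
  if (is.unsorted(sizes, strictly = TRUE))
    stop("window sizes must be strictly increasing")
  structure(sizes, class = "scale_grid")
}

as_scale_grid <- function(x) {
  if (inherits(x, "scale_grid")) x else scale_grid(x)
}

#' @export
print.scale_grid <- function(x, ...) {
  cat("scale grid:", paste0(unclass(x), "x", unclass(x), collapse = ", "), "\n")
  invisible(x)
}
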