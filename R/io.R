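#' Read a grayscale image from PNG or TIFF
#'
#' 8- or 16-bit input is mapped to `[0, 1]`; RGB input is converted to
#' grayscale by luminance (see [to_grayscale()]). TIFF support requires the
#' `tiff` package.
#'
#' @param path image file path (`.png`, `.tif`, `.tiff`).
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext)
  to_grayscale(img)
}

#' Read a binary lesion mask
#'
#' Any strictly positive pixel is treated as lesion, so masks stored with
#' values {0, 1} or {0, 255} both work.
#'
#' @param path single-channel PNG/TIFF file path.
#' @return 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  matrix(as.integer(m > 0), nrow(m), ncol(m))
}

#' Write a probability heatmap to disk
#'
#' Writes a grayscale PNG preview plus a float sidecar CSV with the exact
#' per-pixel probabilities; the sidecar is the authoritative record (the
#' PNG is quantized to the writer's bit depth).
#'
#' @param hm a `probability_heatmap` or numeric matrix in `[0, 1]`.
#' @param path output PNG path; the sidecar is `path` with extension
#'   `.csv`.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(hm, path) {
  probs <- if (inherits(hm, "probability_heatmap")) hm$probs else hm
  png::writePNG(probs, path, asp = NULL)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".csv")
  utils::write.table(probs, sidecar, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Serialize a feature set to a columnar table
#'
#' Writes one row per (pixel, scale) with columns `row`, `col`, `family`,
#' `scale`, and the descriptor values `d1..dk`, for caching extracted
#' features on disk as plain CSV.
#'
#' @param fs a `multiscale_features` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fs, path) {
  stopifnot(inherits(fs, "multiscale_features"))
  tabs <- lapply(seq_along(fs$scales), function(s) {
    d <- fs$desc[[s]]
    colnames(d) <- paste0("d", seq_len(ncol(d)))
    data.frame(row = fs$coords[, 1L], col = fs$coords[, 2L],
               family = fs$family, scale = unclass(fs$scales)[s], d)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature set written by [write_feature_table()]
#' @param path CSV file path.
#' @return a `multiscale_features` object.
#' @export
read_feature_table <- function(path) {
  x <- utils::read.csv(path)
  scales <- scale_grid(sort(unique(x$scale)))
  first <- x[x$scale == unclass(scales)[1L], ]
  coords <- cbind(row = first$row, col = first$col)
  dcols <- grep("^d[0-9]+$", names(x), value = TRUE)
  desc <- lapply(unclass(scales), function(k) {
    block <- as.matrix(x[x$scale == k, dcols, drop = FALSE])
    dimnames(block) <- NULL
    if (x$family[1L] == "lbp") storage.mode(block) <- "integer"
    block
  })
  names(desc) <- as.character(unclass(scales))
  structure(list(family = x$family[1L], scales = scales, coords = coords,
                 desc = desc),
            class = "multiscale_features")
}
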