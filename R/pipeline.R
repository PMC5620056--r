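#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline with the defaults used
#' throughout: scale grid `c(3, 5, 7)`; all four texture families; LBP with
#' 8 bits; Gabor angles 0/90/180 degrees; 32 Haralick gray levels; ridge
#' `alpha = 0.1` and sparsity `eta = 0.001` (`mu` is accepted as an alias
#' for `eta`); selection threshold `sigma = 0.3`; SLIC `rSize = 8`,
#' `reqStr = 0.01`; 50 forest trees; up to 2000 sampled pairs per slice and
#' kind for the distance kernels.
#'
#' @param scales window scale grid (see [scale_grid()]).
#' @param families subset of `c("lbp", "gabor", "haralick", "phow")`.
#' @param bits,rotation_invariant LBP parameters.
#' @param angles Gabor orientations in degrees.
#' @param gray_levels Haralick quantization levels.
#' @param alpha,eta scale-learning regularization controllers.
#' @param mu alias for `eta`; used if `eta` is missing.
#' @param sigma scale-selection threshold in (0, 1).
#' @param rSize,reqStr SLIC superpixel parameters.
#' @param n_trees Random Forest size.
#' @param pairs_per_slice cap on sampled distance pairs per slice and kind.
#' @return a list of class `discrn_config`.
#' @export
discrn_config <- function(scales = c(3, 5, 7), families = FAMILIES,
                          bits = 8L, rotation_invariant = FALSE,
                          angles = c(0, 90, 180), gray_levels = 32L,
                          alpha = 0.1, eta = NULL, mu = NULL, sigma = 0.3,
                          rSize = 8L, reqStr = 0.01, n_trees = 50L,
                          pairs_per_slice = 2000L) {
  if (is.null(eta)) eta <- if (is.null(mu)) 0.001 else mu
  families <- match.arg(families, FAMILIES, several.ok = TRUE)
  structure(
    list(scales = as_scale_grid(scales), families = families,
         bits = as.integer(bits), rotation_invariant = rotation_invariant,
         angles = angles, gray_levels = as.integer(gray_levels),
         alpha = alpha, eta = eta, sigma = sigma,
         rSize = as.integer(rSize), reqStr = reqStr,
         n_trees = as.integer(n_trees),
         pairs_per_slice = as.integer(pairs_per_slice)),
    class = "discrn_config"
  )
}

#' Fit the scale-learning detection pipeline
#'
#' End-to-end training on a set of slices: SLIC superpixels and balanced
#' sampling per slice, multi-scale feature extraction at the sampled pixels,
#' per-family distance kernels and scale-weight learning, scale selection,
#' and a Random Forest on the concatenated selected-scale descriptors.
#' With `select = "all"` the scale-learning step is skipped and every scale
#' is used (the all-scales comparator).
#'
#' @param images list of numeric image matrices (one per slice).
#' @param masks list of binary lesion masks, same shapes.
#' @param config a [discrn_config()].
#' @param seed integer seed driving sampling and the forest.
#' @param select `"discrn"` (learn and select scales) or `"all"`.
#' @param verbose print per-family selected scales.
#' @return an object of class `discrn_model`: `config`, `weights` (named
#'   list of `scale_weights`, `NULL` when `select = "all"`), `selected`
#'   (named list of scale indices), `rf`, `n_pairs_selected`,
#'   `n_pairs_total`.
#' @export
discrn_fit <- function(images, masks, config = discrn_config(), seed = 1L,
                       select = c("discrn", "all"), verbose = FALSE) {
  select <- match.arg(select)
  stopifnot(length(images) == length(masks), length(images) >= 1L)
  S <- length(config$scales)
  n_slices <- length(images)

  samples <- vector("list", n_slices)
  for (t in seq_len(n_slices)) {
    spx <- segment_superpixels(images[[t]], config$rSize, config$reqStr)
    samples[[t]] <- sample_balanced_training(masks[[t]], spx,
                                             seed = seed + 1000L * t)
  }
  # all-scales features at the sampled pixels, per family and slice
  feats <- lapply(config$families, function(fam) {
    list(
      pos = lapply(seq_len(n_slices), function(t)
        extract_family(images[[t]], samples[[t]]$positive, fam,
                       config$scales, config)),
      neg = lapply(seq_len(n_slices), function(t)
        extract_family(images[[t]], samples[[t]]$negative, fam,
                       config$scales, config))
    )
  })
  names(feats) <- config$families

  weights <- NULL
  if (select == "discrn") {
    weights <- lapply(config$families, function(fam) {
      kern <- build_distance_kernels(feats[[fam]]$pos, feats[[fam]]$neg,
                                     pairs_per_slice = config$pairs_per_slice,
                                     seed = seed)
      learn_scale_weights(kern, alpha = config$alpha, eta = config$eta,
                          sigma = config$sigma)
    })
    names(weights) <- config$families
    selected <- lapply(weights, `[[`, "selected")
  } else {
    selected <- stats::setNames(
      rep(list(seq_len(S)), length(config$families)), config$families)
  }
  n_sel <- sum(lengths(selected))
  n_tot <- length(config$families) * S
  if (verbose) {
    for (fam in config$families)
      message(sprintf("family %-8s selected scales: %s", fam,
        paste(unclass(config$scales)[selected[[fam]]], collapse = ", ")))
    message(sprintf("descriptor (family, scale) pairs: %d of %d (%.0f%%)",
                    n_sel, n_tot, 100 * n_sel / n_tot))
  }

  X <- do.call(cbind, lapply(config$families, function(fam) {
    sel <- selected[[fam]]
    rbind(
      do.call(rbind, lapply(feats[[fam]]$pos, function(f)
        do.call(cbind, f$desc[sel]))),
      do.call(rbind, lapply(feats[[fam]]$neg, function(f)
        do.call(cbind, f$desc[sel])))
    )
  }))
  n_pos_all <- sum(vapply(samples, function(s) nrow(s$positive), 1L))
  n_neg_all <- sum(vapply(samples, function(s) nrow(s$negative), 1L))
  # rows: positives of all slices, then negatives of all slices, per family;
  # families share the same row order so cbind above is aligned
  y <- c(rep(1L, n_pos_all), rep(0L, n_neg_all))
  rf <- train_classifier(X, y, n_trees = config$n_trees, seed = seed)
  structure(
    list(config = config, weights = weights, selected = selected, rf = rf,
         n_pairs_selected = n_sel, n_pairs_total = n_tot, seed = seed),
    class = "discrn_model"
  )
}

#' @export
print.discrn_model <- function(x, ...) {
  cat(sprintf("discrn_model: %d families, %d/%d (family, scale) pairs\n",
              length(x$config$families), x$n_pairs_selected,
              x$n_pairs_total))
  for (fam in x$config$families)
    cat(sprintf("  %-8s scales %s\n", fam,
        paste(unclass(x$config$scales)[x$selected[[fam]]], collapse = ", ")))
  invisible(x)
}

#' Exhaustive pixel classification of an image
#'
#' Extracts features at the model's selected scales only, for every pixel of
#' the image, and returns the raw (unquantized) per-pixel lesion-probability
#' heatmap. Deterministic given the model and image.
#'
#' @param model a [discrn_fit()] model.
#' @param image numeric image matrix.
#' @return an unquantized `probability_heatmap`.
#' @export
classify_image <- function(model, image) {
  stopifnot(inherits(model, "discrn_model"))
  if (any(lengths(model$selected) == 0L))
    stop("a feature family has an empty scale selection")
  config <- model$config
  H <- nrow(image); W <- ncol(image)
  pixels <- cbind(rep(seq_len(H), times = W), rep(seq_len(W), each = H))
  X <- do.call(cbind, lapply(config$families, function(fam) {
    sel_sizes <- unclass(config$scales)[model$selected[[fam]]]
    f <- extract_family(image, pixels, fam, scale_grid(sel_sizes), config)
    do.call(cbind, f$desc)
  }))
  probs <- matrix(predict_proba(model$rf, X), H, W)
  new_heatmap(probs, quantized = FALSE)
}

#' Predict a smoothed probability heatmap for a test image
#'
#' Runs [classify_image()], recomputes SLIC superpixels on the test image
#' with the model's `rSize`/`reqStr`, and applies majority-vote smoothing
#' ([smooth_heatmap()]).
#'
#' @inheritParams classify_image
#' @param smooth apply superpixel majority-vote smoothing (default `TRUE`).
#' @return a `probability_heatmap` (quantized when `smooth = TRUE`).
#' @export
discrn_predict <- function(model, image, smooth = TRUE) {
  hm <- classify_image(model, image)
  if (!smooth) return(hm)
  spx <- segment_superpixels(image, model$config$rSize, model$config$reqStr)
  smooth_heatmap(hm, spx)
}
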