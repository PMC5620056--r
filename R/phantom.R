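#' Specification of a synthetic textured phantom
#'
#' Describes a seeded two-class textured image with an elliptical lesion
#' whose texture differs from the background only in the amplitude of an
#' oriented sinusoidal grating whose spatial period equals `planted_scale`.
#' The grating amplitude is `base_amplitude` in the background and
#' `base_amplitude * (1 + effect_size)` inside the lesion, so
#' `effect_size = 0` makes the two classes statistically indistinguishable
#' and larger values concentrate the class difference at the planted window
#' scale.
#'
#' @param height,width image size in pixels.
#' @param center lesion ellipse center `(row, col)`; image center by default.
#' @param axes lesion ellipse semi-axes `(row, col)` in pixels.
#' @param planted_scale window size (odd, >= 3) carrying the class
#'   difference; also the grating period in pixels.
#' @param effect_size relative lesion-vs-background amplitude contrast of
#'   the grating (>= 0); 1.5 by default.
#' @param noise_sd additive i.i.d. Gaussian noise sd; 0.05 by default.
#' @param base_amplitude background grating amplitude; 0.08 by default.
#' @param orientation grating orientation in degrees; 45 by default.
#' @param seed integer seed; phantom generation is a pure function of the
#'   spec.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128L, width = 128L,
                         center = c(height / 2, width / 2),
                         axes = c(height / 5, width / 6),
                         planted_scale = 5L, effect_size = 1.5,
                         noise_sd = 0.05, base_amplitude = 0.08,
                         orientation = 45, seed = 1L) {
  stopifnot(height >= 8L, width >= 8L, length(center) == 2L,
            length(axes) == 2L, effect_size >= 0, noise_sd >= 0,
            base_amplitude > 0)
  planted_scale <- as.integer(planted_scale)
  if (planted_scale < 3L || planted_scale %% 2L == 0L)
    stop("planted_scale must be an odd window size >= 3")
  if (center[1] - axes[1] < 1 || center[1] + axes[1] > height ||
      center[2] - axes[2] < 1 || center[2] + axes[2] > width)
    stop("lesion ellipse exceeds the image bounds")
  structure(
    list(height = as.integer(height), width = as.integer(width),
         center = as.numeric(center), axes = as.numeric(axes),
         planted_scale = planted_scale, effect_size = effect_size,
         noise_sd = noise_sd, base_amplitude = base_amplitude,
         orientation = orientation, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a synthetic phantom image and lesion mask
#'
#' The image is `0.5 + A(pixel) * grating + noise`: an oriented sinusoidal
#' grating with period `planted_scale` (random phase, seeded), whose
#' amplitude is `base_amplitude` in the background and
#' `base_amplitude * (1 + effect_size)` inside the elliptical lesion, plus
#' i.i.d. Gaussian noise of sd `noise_sd`. Intensities are clipped to
#' `[0, 1]`. Identical specs (including seed) give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return a list with `image` (numeric matrix in `[0, 1]`), `mask` (0/1
#'   integer matrix) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  mask <- ((rr - spec$center[1]) / spec$axes[1])^2 +
          ((cc - spec$center[2]) / spec$axes[2])^2 <= 1
  with_seed(spec$seed, {
    phase <- runif(1, 0, 2 * pi)
    th <- spec$orientation * pi / 180
    carrier <- sin(2 * pi * (cc * cos(th) + rr * sin(th)) /
                     spec$planted_scale + phase)
    amp <- spec$base_amplitude * (1 + spec$effect_size * mask)
    img <- 0.5 + amp * carrier + spec$noise_sd * matrix(rnorm(H * W), H, W)
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = matrix(as.integer(mask), H, W), spec = spec)
  })
}

#' Synthetic distance kernels with a planted discriminative scale
#'
#' Direct test harness for the scale-learning core: within-class distance
#' vectors are homogeneous across scales (absolute-normal with mean about
#' 1), while between-class distances at scale `s_star` are drawn with mean
#' `gap` times the other scales. Returns a fully assembled
#' `distance_kernels` object (single slice).
#'
#' @param S number of scales.
#' @param s_star planted scale index in `1..S`.
#' @param gap between-class mean multiplier at the planted scale (> 1 for a
#'   discriminative fixture; `gap = 1` makes the scales exchangeable).
#' @param n_pairs number of sampled pairs per kernel (>= 2).
#' @param seed integer seed.
#' @return a `distance_kernels` object.
#' @export
generate_kernel_fixture <- function(S, s_star, gap, n_pairs, seed = 1L) {
  stopifnot(S >= 1L, s_star >= 1L, s_star <= S, gap >= 1)
  if (n_pairs < 2L) stop("n_pairs must be >= 2")
  with_seed(seed, {
    H_p <- matrix(abs(rnorm(S * n_pairs, mean = 1, sd = 0.2)), S, n_pairs)
    H_b <- matrix(abs(rnorm(S * n_pairs, mean = 1, sd = 0.2)), S, n_pairs)
    H_b[s_star, ] <- abs(rnorm(n_pairs, mean = gap, sd = 0.2 * gap))
    S_p <- H_p %*% t(H_p)
    S_b <- H_b %*% t(H_b)
    ridge <- 1e-8 * sum(diag(S_p)) / S
    structure(
      list(H_p = H_p, H_b = H_b, S_p = S_p, S_b = S_b,
           R_p = chol(S_p + diag(ridge, S)), ridge = ridge,
           slice_p = rep(1L, n_pairs), slice_b = rep(1L, n_pairs),
           family = "synthetic", scales = seq_len(S)),
      class = "distance_kernels"
    )
  })
}
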