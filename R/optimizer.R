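#' Closed-form update of the auxiliary regression vector
#'
#' For fixed scale weights `w`, the auxiliary vector is
#' `a = solve(t(R_p), S_b %*% w) / sqrt(t(w) %*% S_b %*% S_b %*% w)`,
#' i.e. a triangular solve against the Cholesky factor of the intra-class
#' kernel, normalized by the norm of `S_b %*% w`. The update is invariant to
#' positive rescaling of `w`.
#'
#' @param kernels a [build_distance_kernels()] result.
#' @param w numeric weight vector of length `S`.
#' @return numeric vector `a` of length `S`.
#' @export
update_a <- function(kernels, w) {
  Sbw <- as.numeric(kernels$S_b %*% w)
  denom <- sqrt(sum(Sbw^2))
  if (!(denom > 0))
    stop(structure(
      class = c("discrn_nondiscriminative", "error", "condition"),
      list(message = "S_b %*% w is zero: no scale discriminates for this w",
           call = sys.call())
    ))
  as.numeric(backsolve(kernels$R_p, Sbw, transpose = TRUE)) / denom
}

#' Sparse nonnegative least-squares update of the scale weights
#'
#' For fixed `a`, the weights solve
#' `min_{w >= 0} || t(H_b) %*% solve(R_p) %*% a - t(H_b) %*% w ||^2
#'  + alpha * ||w||^2 + eta * ||w||_1`,
#' a nonnegative quadratic program (the l1 term is linear on the
#' nonnegative orthant). Solved by an active-set method in the style of
#' Lawson-Hanson NNLS, working on the normal equations
#' `G = S_b + alpha * I`, `cvec = S_b %*% solve(R_p, a)`; the KKT residual
#' of the returned solution is below `1e-8` (relative to the problem scale).
#'
#' @inheritParams update_a
#' @param a auxiliary vector (length `S`).
#' @param alpha ridge controller (>= 0), 0.1 by default.
#' @param eta l1 sparsity controller (>= 0), 0.001 by default.
#' @return nonnegative numeric weight vector of length `S` (not normalized).
#' @export
solve_w <- function(kernels, a, alpha = 0.1, eta = 0.001) {
  stopifnot(alpha >= 0, eta >= 0)
  S <- nrow(kernels$S_b)
  G <- kernels$S_b + diag(alpha, S)
  cvec <- as.numeric(kernels$S_b %*% backsolve(kernels$R_p, a))
  snnls_active_set(G, cvec, eta)
}

# Active-set solver for min_w  w'Gw - 2c'w + eta*1'w  s.t. w >= 0,
# with G symmetric positive semidefinite. Singular passive-set systems are
# handled by a tiny jitter (they arise only for alpha = 0 with collinear
# distance columns).
snnls_active_set <- function(G, cvec, eta, max_iter = 200L) {
  S <- length(cvec)
  # gradient-sized and solution-sized quantities live on different scales
  # (G can be many orders larger than c), so they get separate tolerances
  tol_g <- 1e-10 * max(1, abs(cvec))
  jitter <- 1e-12 * max(diag(G), 1)
  w <- numeric(S)
  passive <- rep(FALSE, S)
  solve_passive <- function(idx) {
    Gpp <- G[idx, idx, drop = FALSE]
    rhs <- cvec[idx] - eta / 2
    tryCatch(as.numeric(solve(Gpp, rhs)),
             error = function(e)
               as.numeric(solve(Gpp + diag(jitter, length(idx)), rhs)))
  }
  for (iter in seq_len(max_iter)) {
    g <- 2 * (as.numeric(G %*% w) - cvec) + eta
    cand <- which(!passive & g < -tol_g)
    if (length(cand) == 0L) break
    j <- cand[which.min(g[cand])]
    passive[j] <- TRUE
    repeat {
      idx <- which(passive)
      z <- solve_passive(idx)
      if (all(z > 0)) { w[] <- 0; w[idx] <- z; break }
      wp <- w[idx]
      bad <- z <= 0
      tstep <- min(wp[bad] / (wp[bad] - z[bad]))
      wnew <- wp + tstep * (z - wp)
      w[] <- 0
      w[idx] <- wnew
      drop_i <- idx[wnew <= 1e-12 * max(wnew, 0)]
      w[drop_i] <- 0
      passive[drop_i] <- FALSE
      if (!any(passive)) break
    }
  }
  w
}

# Objective of the relaxed least-squares formulation at (a, w):
# || t(H_b) %*% solve(R_p) - t(H_b) %*% w %*% t(a) ||_F^2 + eta * ||w||_1
relaxed_objective <- function(kernels, a, w, eta = 0) {
  M <- t(backsolve(kernels$R_p, kernels$H_b, transpose = TRUE))
  Rsd <- M - outer(as.numeric(t(kernels$H_b) %*% w), a)
  sum(Rsd^2) + eta * sum(abs(w))
}

#' Learn sparse nonnegative scale weights by alternating least squares
#'
#' Starting from uniform weights `w = 1/S`, alternates the closed-form
#' update of the auxiliary vector ([update_a()]) with the sparse nonnegative
#' least-squares update of the weights ([solve_w()]) until the relative
#' change of `w` falls below `tol` or `max_iter` iterations are reached. The
#' final weights are rescaled to unit Euclidean norm. If no scale
#' discriminates (the inter-class kernel maps `w` to zero, or the weights
#' collapse to zero), uniform fallback weights are returned with
#' `fallback = TRUE` and a warning.
#'
#' @inheritParams solve_w
#' @param max_iter maximum number of alternations (>= 1), 100 by default.
#' @param tol relative-change stopping tolerance on `w`, 1e-6 by default.
#' @param sigma selection threshold in (0, 1) used to populate `selected`;
#'   0.3 by default (see [select_scales()]).
#' @param seed kept for interface symmetry; the procedure is deterministic
#'   given the kernels.
#' @return an object of class `scale_weights`: `w` (unit-norm, nonnegative),
#'   `selected`, `w_max`, `a`, `alpha`, `eta`, `sigma`, `iterations`,
#'   `converged`, `fallback`, and the per-iteration `objective` trace of the
#'   relaxed least-squares objective.
#' @export
learn_scale_weights <- function(kernels, alpha = 0.1, eta = 0.001,
                                max_iter = 100L, tol = 1e-6, sigma = 0.3,
                                seed = NULL) {
  stopifnot(max_iter >= 1L)
  S <- nrow(kernels$S_b)
  w <- rep(1 / S, S)
  a <- NULL
  converged <- FALSE
  fallback <- FALSE
  objective <- numeric(0)
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    a_new <- tryCatch(update_a(kernels, w),
                      discrn_nondiscriminative = function(e) NULL)
    if (is.null(a_new)) { fallback <- TRUE; break }
    a <- a_new
    w_new <- solve_w(kernels, a, alpha = alpha, eta = eta)
    objective <- c(objective, relaxed_objective(kernels, a, w_new, eta))
    delta <- sqrt(sum((w_new - w)^2)) / max(sqrt(sum(w^2)), 1e-12)
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (fallback || !any(w > 0)) {
    if (!fallback)
      warning("weights collapsed to zero; returning uniform fallback weights")
    else
      warning("no scale discriminates; returning uniform fallback weights")
    fallback <- TRUE
    w <- rep(1 / S, S)
  }
  w <- w / sqrt(sum(w^2))
  sw <- structure(
    list(w = w, w_max = max(w), a = a, alpha = alpha, eta = eta,
         sigma = sigma, iterations = iter, converged = converged,
         fallback = fallback, objective = objective,
         scales = kernels$scales, family = kernels$family),
    class = "scale_weights"
  )
  sw$selected <- select_scales(sw, sigma)
  sw
}

#' Select the discriminative scales from learned weights
#'
#' Keeps every scale whose weight is at least `sigma` times the maximum
#' weight: `selected = which(w >= sigma * max(w))`. The argmax is always
#' included; decreasing `sigma` can only grow the set.
#'
#' @param w a `scale_weights` object or a nonnegative numeric vector.
#' @param sigma threshold in (0, 1); 0.3 by default.
#' @return integer vector of selected scale indices (1-based).
#' @export
select_scales <- function(w, sigma = 0.3) {
  if (inherits(w, "scale_weights")) w <- w$w
  stopifnot(sigma > 0, sigma < 1)
  if (!any(w > 0)) stop("all weights are zero: no scale can be selected")
  which(w >= sigma * max(w))
}

#' @export
print.scale_weights <- function(x, ...) {
  cat(sprintf("scale_weights (%s): w = %s\n", x$family,
              paste(sprintf("%.4f", x$w), collapse = ", ")))
  cat(sprintf("  selected scales: %s (sigma = %g)%s\n",
              paste(unclass(x$scales)[x$selected], collapse = ", "), x$sigma,
              if (x$fallback) " [uniform fallback]" else ""))
  invisible(x)
}

#' Serialize learned scale weights to JSON
#'
#' @param sw a `scale_weights` object.
#' @param path output file path.
#' @export
write_scale_weights <- function(sw, path) {
  jsonlite::write_json(
    list(family = sw$family, scales = as.integer(unclass(sw$scales)),
         w = sw$w, selected = sw$selected, sigma = sw$sigma,
         alpha = sw$alpha, eta = sw$eta, iterations = sw$iterations,
         converged = sw$converged, fallback = sw$fallback),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read scale weights written by [write_scale_weights()]
#' @param path JSON file path.
#' @return a `scale_weights` object.
#' @export
read_scale_weights <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(w = x$w, w_max = max(x$w), a = NULL, alpha = x$alpha, eta = x$eta,
         sigma = x$sigma, iterations = x$iterations, converged = x$converged,
         fallback = x$fallback, objective = numeric(0),
         scales = scale_grid(x$scales), family = x$family,
         selected = as.integer(x$selected)),
    class = "scale_weights"
  )
}
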