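# Independent explicit-loop oracles for the texture extractors. These
# re-derive every descriptor from its definition with plain R loops and are
# deliberately written without reusing any package internals (including the
# padding helper: reflection is done by index arithmetic here).

# reflect an out-of-range 1-based index about the image edge (edge pixel not
# duplicated)
refl_idx <- function(i, n) {
  if (i < 1) 2 - i else if (i > n) 2 * n - i else i
}

img_at <- function(img, r, c) {
  img[refl_idx(r, nrow(img)), refl_idx(c, ncol(img))]
}

# bilinear sample at fractional (r, c), reflecting at the borders
img_bilinear <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  (1 - fr) * (1 - fc) * img_at(img, r0, c0) +
    (1 - fr) * fc * img_at(img, r0, c0 + 1) +
    fr * (1 - fc) * img_at(img, r0 + 1, c0) +
    fr * fc * img_at(img, r0 + 1, c0 + 1)
}

oracle_lbp <- function(img, r, c, k, bits = 8L) {
  rad <- (k - 1) / 2
  center <- img[r, c]
  code <- integer(bits)
  for (j in seq_len(bits) - 1L) {
    th <- 2 * pi * j / bits
    dr <- -rad * sin(th); dc <- rad * cos(th)
    if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)  # documented snapping
    if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
    v <- img_bilinear(img, r + dr, c + dc)
    code[j + 1L] <- as.integer(v >= center - 1e-12 * max(1, abs(center)))
  }
  code
}

oracle_gabor <- function(img, r, c, k, theta_deg) {
  rad <- (k - 1) / 2
  th <- theta_deg * pi / 180
  lambda <- k; sigma <- 0.5 * lambda
  kern <- matrix(0i, k, k)
  for (a in 1:k) for (b in 1:k) {
    dr <- a - rad - 1; dc <- b - rad - 1
    kern[a, b] <- exp(-(dr^2 + dc^2) / (2 * sigma^2)) *
      exp(1i * 2 * pi * (dc * cos(th) + dr * sin(th)) / lambda)
  }
  kern <- kern - mean(kern)
  s <- 0i
  for (a in 1:k) for (b in 1:k)
    s <- s + img_at(img, r - rad + a - 1, c - rad + b - 1) * kern[a, b]
  Mod(s)
}

# pooled, symmetrized, normalized co-occurrence matrix of the k x k window
oracle_glcm <- function(img, r, c, k, G = 32L) {
  rad <- (k - 1) / 2
  w <- matrix(0, k, k)
  for (a in 1:k) for (b in 1:k)
    w[a, b] <- img_at(img, r - rad + a - 1, c - rad + b - 1)
  wmin <- min(w); wmax <- max(w)
  q <- if (wmax > wmin) pmin(floor((w - wmin) / (wmax - wmin) * G), G - 1)
       else w * 0
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  P <- matrix(0, G, G)
  for (o in offs) for (a in 1:k) for (b in 1:k) {
    a2 <- a + o[1]; b2 <- b + o[2]
    if (a2 >= 1 && a2 <= k && b2 >= 1 && b2 <= k) {
      i <- q[a, b] + 1L; j <- q[a2, b2] + 1L
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
  }
  P / sum(P)
}

oracle_haralick <- function(img, r, c, k, G = 32L) {
  P <- oracle_glcm(img, r, c, k, G)
  px <- rowSums(P)
  occ <- which(px > 0)
  xlx <- function(p) ifelse(p > 0, p * log(p), 0)
  lv <- seq_len(G)
  mu <- sum(lv * px)
  varr <- sum((lv - mu)^2 * px)
  ij <- outer(lv, lv, function(i, j) i * j)
  dd <- outer(lv, lv, function(i, j) (i - j)^2)
  f1 <- sum(P^2)
  f2 <- sum(dd * P)
  f3 <- if (varr > 0) (sum(ij * P) - mu^2) / varr else 0
  f4 <- varr
  f5 <- sum(P / (1 + dd))
  psum <- sapply(2:(2 * G), function(s) sum(P[outer(lv, lv, "+") == s]))
  f6 <- sum((2:(2 * G)) * psum)
  f7 <- sum(((2:(2 * G)) - f6)^2 * psum)
  f8 <- -sum(xlx(psum))
  f9 <- -sum(xlx(P))
  pdiff <- sapply(0:(G - 1), function(d)
    sum(P[abs(outer(lv, lv, "-")) == d]))
  dmu <- sum((0:(G - 1)) * pdiff)
  f10 <- sum(((0:(G - 1)) - dmu)^2 * pdiff)
  f11 <- -sum(xlx(pdiff))
  pxy <- outer(px, px)
  hxy1 <- -sum(P[P > 0] * log(pxy[P > 0]))
  hxy2 <- -sum(xlx(pxy[occ, occ]))
  hx <- -sum(xlx(px))
  f12 <- if (hx > 0) (f9 - hxy1) / hx else 0
  f13 <- if (length(occ) >= 2) {
    arg <- 1 - exp(-2 * (hxy2 - f9))
    if (arg > 0) sqrt(arg) else 0
  } else 0
  f14 <- if (length(occ) >= 2) {
    Q <- matrix(0, length(occ), length(occ))
    for (a in seq_along(occ)) for (b in seq_along(occ))
      Q[a, b] <- sum(P[occ[a], occ] * P[occ[b], occ] / (px[occ[a]] * px[occ]))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (is.finite(ev[2]) && ev[2] > 0) sqrt(ev[2]) else 0
  } else 0
  c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13, f14)
}

oracle_sift <- function(img, r, c, k) {
  B <- ceiling(k / 4)
  half <- 2 * B
  d <- numeric(128)
  for (di in 0:(4 * B - 1)) for (dj in 0:(4 * B - 1)) {
    rr <- r - half + 1 + di; cc <- c - half + 1 + dj
    gx <- (img_at(img, rr, cc + 1) - img_at(img, rr, cc - 1)) / 2
    gy <- (img_at(img, rr + 1, cc) - img_at(img, rr - 1, cc)) / 2
    m <- sqrt(gx^2 + gy^2)
    if (m <= 0) next
    th <- atan2(gy, gx)
    if (th < 0) th <- th + 2 * pi
    ob <- min(floor(th / (pi / 4)), 7)
    sb <- (di %/% B) * 4 + dj %/% B
    d[sb * 8 + ob + 1] <- d[sb * 8 + ob + 1] + m
  }
  n <- sqrt(sum(d^2))
  if (n < 1e-10) return(numeric(128))
  d <- pmin(d / n, 0.2)
  n <- sqrt(sum(d^2))
  if (n > 0) d <- d / n
  d
}

# exhaustive active-set enumeration oracle for the sparse nonnegative
# least-squares step: minimizes w'Gw - 2c'w + eta*1'w over w >= 0 by trying
# every support set
oracle_snnls <- function(G, cvec, eta) {
  S <- length(cvec)
  obj <- function(w) sum(w * (G %*% w)) - 2 * sum(cvec * w) + eta * sum(w)
  best <- numeric(S); best_obj <- 0  # w = 0
  for (m in 1:(2^S - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(S) - 1)) > 0)
    z <- tryCatch(solve(G[idx, idx, drop = FALSE], cvec[idx] - eta / 2),
                  error = function(e) NULL)
    if (is.null(z) || any(z < 0)) next
    w <- numeric(S); w[idx] <- z
    if (obj(w) < best_obj) { best <- w; best_obj <- obj(w) }
  }
  list(w = best, objective = best_obj)
}

# objective of the w-subproblem in its natural (residual) form
wstep_objective <- function(kern, a, w, alpha, eta) {
  y <- as.numeric(t(kern$H_b) %*% backsolve(kern$R_p, a))
  r <- y - as.numeric(t(kern$H_b) %*% w)
  sum(r^2) + alpha * sum(w^2) + eta * sum(abs(w))
}
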