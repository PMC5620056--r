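// Per-pixel multi-scale texture descriptors.
//
// All entry points operate on a pre-padded numeric image matrix (R
// orientation: image(row, col)) and a list of 1-based pixel coordinates
// given in the padded frame. Padding and coordinate shifting happen on the
// R side so that train and test paths share one convention.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double bilinear(const NumericMatrix& img, double r, double c) {
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double fr = r - r0, fc = c - c0;
  return (1.0 - fr) * (1.0 - fc) * img(r0, c0) +
         (1.0 - fr) * fc         * img(r0, c0 + 1) +
         fr         * (1.0 - fc) * img(r0 + 1, c0) +
         fr         * fc         * img(r0 + 1, c0 + 1);
}

// Local binary pattern codes on a circle of radius `radius`.
// Bit j (j = 0..bits-1) samples angle 2*pi*j/bits at offset
// (-radius*sin, +radius*cos) from the center; bit = 1 when the (bilinearly
// interpolated) neighbor intensity is >= the center intensity.
// [[Rcpp::export]]
IntegerMatrix cpp_lbp(const NumericMatrix& img, const IntegerVector& rows,
                      const IntegerVector& cols, double radius, int bits,
                      bool rotation_invariant) {
  const int n = rows.size();
  IntegerMatrix out(n, bits);
  std::vector<double> dr(bits), dc(bits);
  for (int j = 0; j < bits; ++j) {
    double th = 2.0 * M_PI * j / bits;
    dr[j] = -radius * std::sin(th);
    dc[j] =  radius * std::cos(th);
    // snap near-integer offsets so axis-aligned samples read pixels exactly
    if (std::fabs(dr[j] - std::round(dr[j])) < 1e-9) dr[j] = std::round(dr[j]);
    if (std::fabs(dc[j] - std::round(dc[j])) < 1e-9) dc[j] = std::round(dc[j]);
  }
  std::vector<int> code(bits), best(bits), rot(bits);
  for (int i = 0; i < n; ++i) {
    int r = rows[i] - 1, c = cols[i] - 1;
    double center = img(r, c);
    // tolerance absorbs bilinear rounding so exact ties resolve to 1
    double eps = 1e-12 * std::max(1.0, std::fabs(center));
    for (int j = 0; j < bits; ++j)
      code[j] = (bilinear(img, r + dr[j], c + dc[j]) >= center - eps) ? 1 : 0;
    if (rotation_invariant) {
      // minimal circular rotation by integer value of the code
      best = code;
      for (int s = 1; s < bits; ++s) {
        for (int j = 0; j < bits; ++j) rot[j] = code[(j + s) % bits];
        for (int j = 0; j < bits; ++j) {
          if (rot[j] != best[j]) {
            if (rot[j] < best[j]) best = rot;
            break;
          }
        }
      }
      code = best;
    }
    for (int j = 0; j < bits; ++j) out(i, j) = code[j];
  }
  return out;
}

// Windowed correlation with a (complex) Gabor kernel, returning the response
// magnitude at each pixel. The kernel is built on the R side (wavelength,
// envelope, DC correction) so that the parameterization stays in one place.
// [[Rcpp::export]]
NumericVector cpp_kernel_response(const NumericMatrix& img,
                                  const IntegerVector& rows,
                                  const IntegerVector& cols,
                                  const NumericMatrix& kre,
                                  const NumericMatrix& kim) {
  const int n = rows.size();
  const int k = kre.nrow();
  const int rad = (k - 1) / 2;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int r = rows[i] - 1, c = cols[i] - 1;
    double sre = 0.0, sim = 0.0;
    for (int a = 0; a < k; ++a)
      for (int b = 0; b < k; ++b) {
        double v = img(r - rad + a, c - rad + b);
        sre += v * kre(a, b);
        sim += v * kim(a, b);
      }
    out[i] = std::sqrt(sre * sre + sim * sim);
  }
  return out;
}

static inline double xlogx(double p) { return p > 0.0 ? p * std::log(p) : 0.0; }

// 14 Haralick statistics of the window co-occurrence matrix.
// Window intensities are quantized to `glev` levels over the window range;
// co-occurrence is accumulated over the four distance-1 offsets
// (0, 45, 90, 135 degrees), symmetrized and normalized, and the statistics
// are computed once on the pooled matrix. Correlation-type statistics are 0
// for degenerate (single-level) windows; the maximal correlation coefficient
// falls back to 0 whenever undefined.
// [[Rcpp::export]]
NumericMatrix cpp_haralick(const NumericMatrix& img, const IntegerVector& rows,
                           const IntegerVector& cols, int win, int glev) {
  const int n = rows.size();
  const int rad = (win - 1) / 2;
  NumericMatrix out(n, 14);
  // offsets (drow, dcol): 0, 45, 90, 135 degrees with rows growing downward
  const int offr[4] = {0, -1, -1, -1};
  const int offc[4] = {1, 1, 0, -1};

  std::vector<int> q(win * win);
  std::vector<double> P(glev * glev), px(glev), psum(2 * glev), pdiff(glev);

  for (int i = 0; i < n; ++i) {
    int r0 = rows[i] - 1, c0 = cols[i] - 1;
    double wmin = R_PosInf, wmax = R_NegInf;
    for (int a = 0; a < win; ++a)
      for (int b = 0; b < win; ++b) {
        double v = img(r0 - rad + a, c0 - rad + b);
        if (v < wmin) wmin = v;
        if (v > wmax) wmax = v;
      }
    bool flat = !(wmax > wmin);
    for (int a = 0; a < win; ++a)
      for (int b = 0; b < win; ++b) {
        double v = img(r0 - rad + a, c0 - rad + b);
        int bin = flat ? 0 : (int)std::floor((v - wmin) / (wmax - wmin) * glev);
        if (bin >= glev) bin = glev - 1;
        q[a * win + b] = bin;  // 0-based level
      }
    std::fill(P.begin(), P.end(), 0.0);
    double tot = 0.0;
    for (int a = 0; a < win; ++a)
      for (int b = 0; b < win; ++b)
        for (int o = 0; o < 4; ++o) {
          int a2 = a + offr[o], b2 = b + offc[o];
          if (a2 < 0 || a2 >= win || b2 < 0 || b2 >= win) continue;
          int la = q[a * win + b], lb = q[a2 * win + b2];
          P[la * glev + lb] += 1.0;  // symmetrized: both directions
          P[lb * glev + la] += 1.0;
          tot += 2.0;
        }
    if (tot > 0) for (double& v : P) v /= tot;

    // occupied levels (0-based)
    std::fill(px.begin(), px.end(), 0.0);
    for (int a = 0; a < glev; ++a)
      for (int b = 0; b < glev; ++b) px[a] += P[a * glev + b];
    std::vector<int> lv;
    for (int a = 0; a < glev; ++a) if (px[a] > 0) lv.push_back(a);
    const int L = (int)lv.size();

    std::fill(psum.begin(), psum.end(), 0.0);
    std::fill(pdiff.begin(), pdiff.end(), 0.0);
    double asm_ = 0.0, contrast = 0.0, idm = 0.0, ent = 0.0, corr_num = 0.0;
    double mu = 0.0, var = 0.0, hxy1 = 0.0, hxy2 = 0.0, hx = 0.0;
    for (int a : lv) mu += (a + 1.0) * px[a];
    for (int a : lv) {
      var += (a + 1.0 - mu) * (a + 1.0 - mu) * px[a];
      hx -= xlogx(px[a]);
      for (int b : lv) {
        double p = P[a * glev + b];
        double pp = px[a] * px[b];
        hxy2 -= xlogx(pp);
        if (p > 0) {
          asm_ += p * p;
          contrast += (a - b) * (a - b) * p;
          idm += p / (1.0 + (a - b) * (a - b));
          ent -= xlogx(p);
          corr_num += (a + 1.0) * (b + 1.0) * p;
          hxy1 -= p * std::log(pp);
          psum[a + b] += p;          // index = (a+1)+(b+1)-2
          pdiff[std::abs(a - b)] += p;
        }
      }
    }
    double correlation = var > 0 ? (corr_num - mu * mu) / var : 0.0;
    double savg = 0.0, svar = 0.0, sent = 0.0;
    for (int k2 = 0; k2 < 2 * glev - 1; ++k2) {
      double p = psum[k2];
      if (p > 0) { savg += (k2 + 2.0) * p; sent -= xlogx(p); }
    }
    for (int k2 = 0; k2 < 2 * glev - 1; ++k2) {
      double p = psum[k2];
      if (p > 0) svar += (k2 + 2.0 - savg) * (k2 + 2.0 - savg) * p;
    }
    double dmu = 0.0, dvar = 0.0, dent = 0.0;
    for (int k2 = 0; k2 < glev; ++k2) {
      double p = pdiff[k2];
      if (p > 0) { dmu += k2 * p; dent -= xlogx(p); }
    }
    for (int k2 = 0; k2 < glev; ++k2) {
      double p = pdiff[k2];
      if (p > 0) dvar += (k2 - dmu) * (k2 - dmu) * p;
    }
    double imc1 = hx > 0 ? (ent - hxy1) / hx : 0.0;  // HX = HY by symmetry
    double imc2 = 0.0;
    if (L >= 2) {
      double arg = 1.0 - std::exp(-2.0 * (hxy2 - ent));
      imc2 = arg > 0 ? std::sqrt(arg) : 0.0;
    }
    double mcc = 0.0;
    if (L >= 2) {
      // Q = Dx^{-1} P Dx^{-1} P' is similar to B^2 with the symmetric
      // B = Dx^{-1/2} P Dx^{-1/2}; its eigenvalues are the squares of B's,
      // so the second-largest eigenvalue of Q comes from a symmetric solve.
      arma::mat B(L, L);
      for (int a = 0; a < L; ++a)
        for (int b = 0; b < L; ++b)
          B(a, b) = P[lv[a] * glev + lv[b]] /
                    std::sqrt(px[lv[a]] * px[lv[b]]);
      arma::vec ev;
      if (arma::eig_sym(ev, B)) {
        arma::vec sq = arma::sort(arma::square(ev), "descend");
        double second = sq(1);
        if (std::isfinite(second) && second > 0) mcc = std::sqrt(second);
      }
    }
    out(i, 0)  = asm_;
    out(i, 1)  = contrast;
    out(i, 2)  = correlation;
    out(i, 3)  = var;
    out(i, 4)  = idm;
    out(i, 5)  = savg;
    out(i, 6)  = svar;
    out(i, 7)  = sent;
    out(i, 8)  = ent;
    out(i, 9)  = dvar;
    out(i, 10) = dent;
    out(i, 11) = imc1;
    out(i, 12) = imc2;
    out(i, 13) = mcc;
  }
  return out;
}

// Dense SIFT-style 128-length descriptor: 4x4 spatial bins of side `binsz`
// pixels around each sample, 8 orientation bins (nearest-lower assignment,
// no interpolation), gradient by central differences, magnitude-weighted.
// L2-normalized, clipped at 0.2, renormalized; flat patches give all-zero
// descriptors.
// [[Rcpp::export]]
NumericMatrix cpp_dense_sift(const NumericMatrix& img, const IntegerVector& rows,
                             const IntegerVector& cols, int binsz) {
  const int n = rows.size();
  const int half = 2 * binsz;
  NumericMatrix out(n, 128);
  std::vector<double> d(128);
  for (int i = 0; i < n; ++i) {
    int r0 = rows[i] - 1, c0 = cols[i] - 1;
    std::fill(d.begin(), d.end(), 0.0);
    for (int di = 0; di < 4 * binsz; ++di)
      for (int dj = 0; dj < 4 * binsz; ++dj) {
        int r = r0 - half + 1 + di, c = c0 - half + 1 + dj;
        double gx = (img(r, c + 1) - img(r, c - 1)) / 2.0;
        double gy = (img(r + 1, c) - img(r - 1, c)) / 2.0;
        double m = std::sqrt(gx * gx + gy * gy);
        if (m <= 0) continue;
        double th = std::atan2(gy, gx);
        if (th < 0) th += 2.0 * M_PI;
        int ob = (int)(th / (M_PI / 4.0));
        if (ob >= 8) ob = 7;
        int sbr = di / binsz, sbc = dj / binsz;
        d[(sbr * 4 + sbc) * 8 + ob] += m;
      }
    double nrm = 0.0;
    for (double v : d) nrm += v * v;
    nrm = std::sqrt(nrm);
    if (nrm < 1e-10) continue;  // flat patch -> all zeros
    for (double& v : d) { v /= nrm; if (v > 0.2) v = 0.2; }
    nrm = 0.0;
    for (double v : d) nrm += v * v;
    nrm = std::sqrt(nrm);
    if (nrm > 0) for (double& v : d) v /= nrm;
    for (int j = 0; j < 128; ++j) out(i, j) = d[j];
  }
  return out;
}
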