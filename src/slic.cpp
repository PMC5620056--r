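// SLIC superpixels for grayscale images: spatially localized k-means over
// (intensity, row, col), with the regularizer scaled as reqStr / rSize^2 so
// that `reqStr` is comparable across superpixel sizes. Cluster centers start
// on a grid with step rSize; assignment is restricted to a 2*rSize window
// around each center. A final pass relabels 4-connected components and
// absorbs components smaller than rSize^2/4 into an adjacent region, so the
// returned labels always form a partition into 4-connected regions.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cpp_slic(const NumericMatrix& img, int rSize, double reqStr,
                       int iters) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);
  if (H < rSize || W < rSize) {
    std::fill(lab.begin(), lab.end(), 1);
    return lab;
  }
  const int gr = (H + rSize - 1) / rSize;  // grid rows
  const int gc = (W + rSize - 1) / rSize;
  int K = gr * gc;
  std::vector<double> cr(K), cc(K), ci(K);
  int k = 0;
  for (int a = 0; a < gr; ++a)
    for (int b = 0; b < gc; ++b, ++k) {
      double r = std::min(H - 1.0, a * rSize + rSize / 2.0);
      double c = std::min(W - 1.0, b * rSize + rSize / 2.0);
      cr[k] = r; cc[k] = c;
      ci[k] = img((int)r, (int)c);
    }
  const double sw = reqStr / (double)(rSize * rSize);  // spatial weight
  std::vector<int> assign(H * W, 0);
  std::vector<double> best(H * W);
  for (int it = 0; it < iters; ++it) {
    std::fill(best.begin(), best.end(), R_PosInf);
    for (int q = 0; q < K; ++q) {
      int rlo = std::max(0, (int)cr[q] - 2 * rSize);
      int rhi = std::min(H - 1, (int)cr[q] + 2 * rSize);
      int clo = std::max(0, (int)cc[q] - 2 * rSize);
      int chi = std::min(W - 1, (int)cc[q] + 2 * rSize);
      for (int r = rlo; r <= rhi; ++r)
        for (int c = clo; c <= chi; ++c) {
          double di = img(r, c) - ci[q];
          double dsp = (r - cr[q]) * (r - cr[q]) + (c - cc[q]) * (c - cc[q]);
          double d = di * di + sw * dsp;
          int idx = r * W + c;
          if (d < best[idx]) { best[idx] = d; assign[idx] = q; }
        }
    }
    std::vector<double> sr(K, 0), sc(K, 0), si(K, 0), cnt(K, 0);
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) {
        int q = assign[r * W + c];
        sr[q] += r; sc[q] += c; si[q] += img(r, c); cnt[q] += 1;
      }
    for (int q = 0; q < K; ++q)
      if (cnt[q] > 0) {
        cr[q] = sr[q] / cnt[q];
        cc[q] = sc[q] / cnt[q];
        ci[q] = si[q] / cnt[q];
      }
  }
  // connected-components relabeling with small-component absorption
  const int minSize = std::max(1, rSize * rSize / 4);
  std::vector<int> out(H * W, 0);
  std::vector<int> stack, comp;
  int nextLab = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      int idx = r * W + c;
      if (out[idx] != 0) continue;
      int q = assign[idx];
      stack.assign(1, idx);
      comp.clear();
      out[idx] = -1;  // visiting marker
      int adj = 0;    // an already-final neighboring label, if any
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        comp.push_back(cur);
        int rr = cur / W, cc2 = cur % W;
        for (int o = 0; o < 4; ++o) {
          int r2 = rr + dr[o], c2 = cc2 + dc[o];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          int i2 = r2 * W + c2;
          if (out[i2] > 0) adj = out[i2];
          else if (out[i2] == 0 && assign[i2] == q) {
            out[i2] = -1;
            stack.push_back(i2);
          }
        }
      }
      int labv;
      if ((int)comp.size() < minSize && adj > 0) labv = adj;
      else labv = ++nextLab;
      for (int cur : comp) out[cur] = labv;
    }
  // compact label ids to 1..K' (absorption can leave gaps only if a label
  // was never assigned, which cannot happen, but relabel defensively)
  std::vector<int> remap(nextLab + 1, 0);
  int used = 0;
  for (int idx = 0; idx < H * W; ++idx) {
    int v = out[idx];
    if (remap[v] == 0) remap[v] = ++used;
  }
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) lab(r, c) = remap[out[r * W + c]];
  return lab;
}
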