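#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// Connected-component labeling of an integer label array (0 = background).
// Two voxels belong to the same region iff they carry the same nonzero
// label and are adjacent under the requested connectivity. `connectivity`
// is the in-plane code: 4 (edge neighbors) or 8 (edge + diagonal); for 3D
// input these generalize to 6- and 26-connectivity respectively. Regions
// are numbered 1..R in order of first encounter along the linear
// (column-major) scan, which makes ties between equal-sized components
// resolvable deterministically by region id.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(IntegerVector labels, IntegerVector dims,
                           int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nx = dims[0];
  int ny = dims.size() > 1 ? dims[1] : 1;
  int nz = dims.size() > 2 ? dims[2] : 1;
  R_xlen_t n = labels.size();
  if (n != (R_xlen_t)nx * ny * nz) stop("dims do not match label length");

  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 4 && man != 1) continue;
        offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
      }
  int noff = (int)offs.size() / 3;

  IntegerVector region(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (labels[idx] == 0 || region[idx] != 0) continue;
    int lab = labels[idx];
    ++next;
    region[idx] = next;
    stack.clear();
    stack.push_back((int)idx);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (int k = 0; k < noff; ++k) {
        int X = x + offs[3 * k], Y = y + offs[3 * k + 1], Z = z + offs[3 * k + 2];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        int nb = X + nx * (Y + ny * Z);
        if (region[nb] == 0 && labels[nb] == lab) {
          region[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  region.attr("dim") = dims;
  return region;
}

// Per-pixel local features over a square sliding window clipped to the
// ROI. For each ROI pixel (coords, 1-based, canonical order) the window
// w x w around it is intersected with the mask; first-order statistics
// are computed on the raw intensities, the entropy and the co-occurrence
// features on the pre-quantized levels (1..nlevels). Windows with fewer
// than 3 valid pixels yield an all-NA row (filled by the caller from the
// nearest valid pixel). Moments use population normalization; zero
// within-window variance sets skewness, kurtosis and GLCM correlation
// to 0. Co-occurrence: symmetric, distance 1, averaged over the four
// 2D directions; windows with no valid pair fall back to the
// single-level convention (contrast 0, homogeneity 1, ASM 1,
// correlation 0).
// [[Rcpp::export(name = ".window_features_cpp")]]
NumericMatrix window_features_cpp(NumericMatrix img, LogicalMatrix mask,
                                  IntegerMatrix quant, IntegerMatrix coords,
                                  int window, int nlevels) {
  int nr = img.nrow(), nc = img.ncol();
  int half = window / 2;
  int npix = coords.nrow();
  NumericMatrix out(npix, 10);
  const int dr[4] = {1, 0, 1, 1};
  const int dc[4] = {0, 1, 1, -1};
  std::vector<double> vals(window * window);
  std::vector<int> lev(window * window);
  std::vector<int> wr(window * window), wc(window * window);
  std::vector<double> hist(nlevels);
  std::vector<double> cc(nlevels * nlevels);
  // window-local lookup of quant level at absolute (r, c), -1 = invalid
  std::vector<int> patch(window * window);

  for (int i = 0; i < npix; ++i) {
    int r0 = coords(i, 0) - 1, c0 = coords(i, 1) - 1;
    int nv = 0;
    std::fill(patch.begin(), patch.end(), -1);
    for (int dc2 = -half; dc2 <= half; ++dc2) {
      for (int dr2 = -half; dr2 <= half; ++dr2) {
        int r = r0 + dr2, c = c0 + dc2;
        if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
        if (!mask(r, c)) continue;
        vals[nv] = img(r, c);
        lev[nv] = quant(r, c);
        wr[nv] = dr2 + half;
        wc[nv] = dc2 + half;
        patch[(dr2 + half) + window * (dc2 + half)] = lev[nv];
        ++nv;
      }
    }
    if (nv < 3) {
      for (int f = 0; f < 10; ++f) out(i, f) = NA_REAL;
      continue;
    }
    // first-order moments (population)
    double m = 0, en = 0;
    for (int j = 0; j < nv; ++j) { m += vals[j]; en += vals[j] * vals[j]; }
    m /= nv; en /= nv;
    double m2 = 0, m3 = 0, m4 = 0;
    for (int j = 0; j < nv; ++j) {
      double d = vals[j] - m;
      m2 += d * d; m3 += d * d * d; m4 += d * d * d * d;
    }
    m2 /= nv; m3 /= nv; m4 /= nv;
    double sd = std::sqrt(m2);
    double skew = 0, kurt = 0;
    if (m2 > 1e-12) {
      skew = m3 / std::pow(m2, 1.5);
      kurt = m4 / (m2 * m2);
    }
    // first-order entropy over quantized levels
    std::fill(hist.begin(), hist.end(), 0.0);
    for (int j = 0; j < nv; ++j) hist[lev[j] - 1] += 1.0;
    double ent = 0;
    for (int l = 0; l < nlevels; ++l) {
      if (hist[l] > 0) {
        double p = hist[l] / nv;
        ent -= p * std::log2(p);
      }
    }
    // symmetric GLCM at distance 1, four directions pooled
    std::fill(cc.begin(), cc.end(), 0.0);
    double tot = 0;
    for (int j = 0; j < nv; ++j) {
      for (int d = 0; d < 4; ++d) {
        int R2 = wr[j] + dr[d], C2 = wc[j] + dc[d];
        if (R2 < 0 || R2 >= window || C2 < 0 || C2 >= window) continue;
        int l2 = patch[R2 + window * C2];
        if (l2 < 0) continue;
        int a = lev[j] - 1, b = l2 - 1;
        cc[a + nlevels * b] += 1.0;
        cc[b + nlevels * a] += 1.0;
        tot += 2.0;
      }
    }
    double contrast, homog, asm_, corr;
    if (tot == 0) {
      contrast = 0; homog = 1; asm_ = 1; corr = 0;
    } else {
      contrast = 0; homog = 0; asm_ = 0;
      double mu = 0, ex2 = 0, exy = 0, psum = 0;
      for (int a = 0; a < nlevels; ++a) {
        for (int b = 0; b < nlevels; ++b) {
          double p = cc[a + nlevels * b] / tot;
          if (p == 0) continue;
          psum += p;
          double diff = a - b;
          contrast += p * diff * diff;
          homog += p / (1.0 + std::abs(diff));
          asm_ += p * p;
          mu += p * a;          // symmetric: row and col marginals equal
          ex2 += p * (double)a * a;
          exy += p * (double)a * b;
        }
      }
      if (std::abs(psum - 1.0) > 1e-9) stop("GLCM probabilities do not sum to 1");
      double var = ex2 - mu * mu;
      corr = (var > 1e-12) ? (exy - mu * mu) / var : 0.0;
    }
    out(i, 0) = m;
    out(i, 1) = sd;
    out(i, 2) = skew;
    out(i, 3) = kurt;
    out(i, 4) = en;
    out(i, 5) = ent;
    out(i, 6) = contrast;
    out(i, 7) = homog;
    out(i, 8) = asm_;
    out(i, 9) = corr;
  }
  return out;
}
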