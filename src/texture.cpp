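#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double xlog2(double p) { return p > 0.0 ? p * std::log2(p) : 0.0; }

// Per-pixel Haralick statistics from windowed grey-level co-occurrence
// matrices. `q` holds quantised levels 1..G over the working box; `roi` marks
// the pixels for which features are wanted. For each ROI pixel a symmetric
// GLCM is accumulated from the four distance-1 offsets over all pixel pairs
// lying inside the centred w x w window (clipped at the box edge), then
// normalised. Returns an nroi x 13 matrix in the canonical feature order:
// contrast energy/inverse moment/average/variance/entropy, intensity
// average/variance/entropy, entropy, energy, correlation, IMC1, IMC2.
// "Contrast" statistics are moments of the |i-j| marginal, "intensity"
// statistics moments of the (i+j)/2 marginal.
// [[Rcpp::export]]
NumericMatrix glcm_haralick_roi(IntegerMatrix q, LogicalMatrix roi,
                                int nlevels, int w) {
  const int H = q.nrow(), W = q.ncol();
  const int half = w / 2;
  const int G = nlevels;
  std::vector<int> roi_r, roi_c;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (roi(r, c)) { roi_r.push_back(r); roi_c.push_back(c); }
  const int n = (int)roi_r.size();
  NumericMatrix out(n, 13);
  const int offr[4] = {0, 1, 1, 1};
  const int offc[4] = {1, 0, 1, -1};
  std::vector<double> glcm((size_t)G * G, 0.0);
  std::vector<int> touched; touched.reserve(256);
  std::vector<double> px(G), py(G), pd(G), ps(2 * G + 1);
  std::vector<char> ilev(G), jlev(G);
  for (int k = 0; k < n; ++k) {
    const int r0 = roi_r[k], c0 = roi_c[k];
    const int rlo = std::max(0, r0 - half), rhi = std::min(H - 1, r0 + half);
    const int clo = std::max(0, c0 - half), chi = std::min(W - 1, c0 + half);
    touched.clear();
    double total = 0.0;
    for (int c = clo; c <= chi; ++c) {
      for (int r = rlo; r <= rhi; ++r) {
        const int a = q(r, c) - 1;
        for (int o = 0; o < 4; ++o) {
          const int r2 = r + offr[o], c2 = c + offc[o];
          if (r2 < rlo || r2 > rhi || c2 < clo || c2 > chi) continue;
          const int b = q(r2, c2) - 1;
          const int i1 = a * G + b, i2 = b * G + a;  // symmetric
          if (glcm[i1] == 0.0) touched.push_back(i1);
          if (i1 == i2) {
            glcm[i1] += 2.0;
          } else {
            glcm[i1] += 1.0;
            if (glcm[i2] == 0.0) touched.push_back(i2);
            glcm[i2] += 1.0;
          }
          total += 2.0;
        }
      }
    }
    if (total == 0.0) {  // 1x1 degenerate window: point-mass GLCM on diagonal
      const int a = q(r0, c0) - 1;
      const int i1 = a * G + a;
      glcm[i1] = 1.0; touched.push_back(i1); total = 1.0;
    }
    std::fill(px.begin(), px.end(), 0.0);
    std::fill(py.begin(), py.end(), 0.0);
    std::fill(pd.begin(), pd.end(), 0.0);
    std::fill(ps.begin(), ps.end(), 0.0);
    std::fill(ilev.begin(), ilev.end(), 0);
    std::fill(jlev.begin(), jlev.end(), 0);
    double ent = 0.0, energy = 0.0, sij = 0.0;
    for (size_t t = 0; t < touched.size(); ++t) {
      const int idx = touched[t];
      const double p = glcm[idx] / total;
      glcm[idx] = p;  // keep normalised for HXY1 pass
      const int i = idx / G, j = idx % G;
      px[i] += p; py[j] += p;
      pd[std::abs(i - j)] += p;
      ps[i + j] += p;
      ilev[i] = 1; jlev[j] = 1;
      ent -= xlog2(p);
      energy += p * p;
      sij += (double)(i + 1) * (double)(j + 1) * p;
    }
    double ca = 0.0, ce = 0.0, cim = 0.0, centp = 0.0;
    for (int d = 0; d < G; ++d) {
      if (pd[d] == 0.0) continue;
      ca += d * pd[d];
      ce += (double)d * d * pd[d];
      cim += pd[d] / (1.0 + (double)d * d);
      centp -= xlog2(pd[d]);
    }
    double cvar = 0.0;
    for (int d = 0; d < G; ++d)
      if (pd[d] > 0.0) cvar += (d - ca) * (d - ca) * pd[d];
    double ia = 0.0, ientp = 0.0;
    for (int s = 0; s <= 2 * (G - 1); ++s) {
      if (ps[s] == 0.0) continue;
      const double m = (s + 2) / 2.0;  // levels are 1-based: (i+1 + j+1)/2
      ia += m * ps[s];
      ientp -= xlog2(ps[s]);
    }
    double ivar = 0.0;
    for (int s = 0; s <= 2 * (G - 1); ++s) {
      if (ps[s] == 0.0) continue;
      const double m = (s + 2) / 2.0;
      ivar += (m - ia) * (m - ia) * ps[s];
    }
    double mux = 0.0, muy = 0.0, hx = 0.0, hy = 0.0;
    for (int i = 0; i < G; ++i) {
      mux += (i + 1) * px[i];
      muy += (i + 1) * py[i];
      hx -= xlog2(px[i]);
      hy -= xlog2(py[i]);
    }
    double sx = 0.0, sy = 0.0;
    for (int i = 0; i < G; ++i) {
      sx += ((i + 1) - mux) * ((i + 1) - mux) * px[i];
      sy += ((i + 1) - muy) * ((i + 1) - muy) * py[i];
    }
    sx = std::sqrt(sx); sy = std::sqrt(sy);
    double corr = (sx > 1e-12 && sy > 1e-12) ? (sij - mux * muy) / (sx * sy) : 0.0;
    // information measures of correlation
    double hxy1 = 0.0;
    for (size_t t = 0; t < touched.size(); ++t) {
      const int idx = touched[t];
      const double p = glcm[idx];
      const int i = idx / G, j = idx % G;
      const double m = px[i] * py[j];
      if (p > 0.0 && m > 0.0) hxy1 -= p * std::log2(m);
    }
    double hxy2 = 0.0;
    for (int i = 0; i < G; ++i) {
      if (!ilev[i] || px[i] == 0.0) continue;
      for (int j = 0; j < G; ++j) {
        if (!jlev[j] || py[j] == 0.0) continue;
        hxy2 -= xlog2(px[i] * py[j]);
      }
    }
    const double hmax = std::max(hx, hy);
    const double imc1 = hmax > 1e-12 ? (ent - hxy1) / hmax : 0.0;
    const double imc2 = std::sqrt(std::max(0.0, 1.0 - std::exp(-2.0 * (hxy2 - ent))));
    out(k, 0) = ce;   out(k, 1) = cim;  out(k, 2) = ca;   out(k, 3) = cvar;
    out(k, 4) = centp; out(k, 5) = ia;  out(k, 6) = ivar; out(k, 7) = ientp;
    out(k, 8) = ent;  out(k, 9) = energy; out(k, 10) = corr;
    out(k, 11) = imc1; out(k, 12) = imc2;
    for (size_t t = 0; t < touched.size(); ++t) glcm[touched[t]] = 0.0;
  }
  return out;
}

// Sliding-window first-order statistics (mean, median, range, sample sd) of
// the centred w x w window (clipped at the box edge) for each ROI pixel.
// Returns an nroi x 4 matrix.
// [[Rcpp::export]]
NumericMatrix window_stats_roi(NumericMatrix img, LogicalMatrix roi, int w) {
  const int H = img.nrow(), W = img.ncol();
  const int half = w / 2;
  std::vector<int> roi_r, roi_c;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (roi(r, c)) { roi_r.push_back(r); roi_c.push_back(c); }
  const int n = (int)roi_r.size();
  NumericMatrix out(n, 4);
  std::vector<double> buf; buf.reserve((size_t)w * w);
  for (int k = 0; k < n; ++k) {
    const int r0 = roi_r[k], c0 = roi_c[k];
    const int rlo = std::max(0, r0 - half), rhi = std::min(H - 1, r0 + half);
    const int clo = std::max(0, c0 - half), chi = std::min(W - 1, c0 + half);
    buf.clear();
    double s = 0.0, mn = R_PosInf, mx = R_NegInf;
    for (int c = clo; c <= chi; ++c)
      for (int r = rlo; r <= rhi; ++r) {
        const double v = img(r, c);
        buf.push_back(v);
        s += v;
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
    const int m = (int)buf.size();
    const double mean = s / m;
    double ss = 0.0;
    for (int i = 0; i < m; ++i) ss += (buf[i] - mean) * (buf[i] - mean);
    const double sd = m > 1 ? std::sqrt(ss / (m - 1)) : 0.0;
    std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
    double med = buf[m / 2];
    if (m % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.begin() + m / 2);
      med = 0.5 * (med + buf[m / 2 - 1]);
    }
    out(k, 0) = mean; out(k, 1) = med; out(k, 2) = mx - mn; out(k, 3) = sd;
  }
  return out;
}
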