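#include <Rcpp.h>
using namespace Rcpp;

// Predicted BOLD time course for a 2-D Gaussian pRF against a stack of
// stimulus masks already resampled to TR resolution, followed by causal
// convolution with an HRF kernel.
//
// maskT: nTR x (heightPx * widthPx) matrix (the transposed pixel-by-time
//        matrix, so each pixel's time course is contiguous in memory);
//        pixel p = (row - 1) + (col - 1) * heightPx occupies column p.
// xs, ys: degree coordinates of pixel-column centres (length widthPx) and
//         pixel-row centres (length heightPx).
// The Gaussian is evaluated inside a +/- truncSd * sigma window and
// normalised by its in-window sum, matching the unit-sum convention of the
// full-grid R reference path to within the truncated tail mass.
static std::vector<double> overlap_series(const NumericMatrix &maskT,
                                          const NumericVector &xs,
                                          const NumericVector &ys,
                                          double x, double y, double sigma,
                                          double truncSd) {
  const int h = ys.size(), w = xs.size(), nT = maskT.nrow();
  const double lim = truncSd * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);

  // ys runs from +extent downward, xs from -extent upward
  int c0 = 0, c1 = w - 1, r0 = 0, r1 = h - 1;
  while (c0 < w && xs[c0] < x - lim) ++c0;
  while (c1 >= 0 && xs[c1] > x + lim) --c1;
  while (r0 < h && ys[r0] > y + lim) ++r0;
  while (r1 >= 0 && ys[r1] < y - lim) --r1;

  std::vector<double> ov(nT, 0.0);
  if (c0 > c1 || r0 > r1) return ov;  // window entirely off-grid

  double wsum = 0.0;
  const double *M = REAL(maskT);
  for (int c = c0; c <= c1; ++c) {
    const double dx2 = (xs[c] - x) * (xs[c] - x);
    for (int r = r0; r <= r1; ++r) {
      const double dy2 = (ys[r] - y) * (ys[r] - y);
      const double wt = std::exp(-(dx2 + dy2) * inv2s2);
      wsum += wt;
      const double *col = M + (size_t)(r + c * h) * nT;
      for (int t = 0; t < nT; ++t) ov[t] += wt * col[t];
    }
  }
  if (wsum > 0) for (int t = 0; t < nT; ++t) ov[t] /= wsum;
  return ov;
}

static std::vector<double> conv_causal(const std::vector<double> &v,
                                       const NumericVector &h) {
  const int n = v.size(), L = h.size();
  std::vector<double> out(n, 0.0);
  for (int t = 0; t < n; ++t) {
    const int kmax = std::min(t, L - 1);
    double acc = 0.0;
    for (int k = 0; k <= kmax; ++k) acc += h[k] * v[t - k];
    out[t] = acc;
  }
  return out;
}

// [[Rcpp::export(name = ".cppPrfPredict")]]
NumericVector cpp_prf_predict(NumericMatrix maskT, NumericVector xs,
                              NumericVector ys, double x, double y,
                              double sigma, NumericVector hrf,
                              double truncSd = 6.0) {
  std::vector<double> ov = overlap_series(maskT, xs, ys, x, y, sigma,
                                          truncSd);
  std::vector<double> pred = conv_causal(ov, hrf);
  return NumericVector(pred.begin(), pred.end());
}

// Sum of squared errors of obs ~ intercept + beta * predicted, with the two
// linear coefficients solved in closed form. Constant predictions fall back
// to the intercept-only model.
// [[Rcpp::export(name = ".cppPrfSSE")]]
double cpp_prf_sse(NumericMatrix maskT, NumericVector xs, NumericVector ys,
                   double x, double y, double sigma, NumericVector hrf,
                   NumericVector obs, double truncSd = 6.0) {
  std::vector<double> ov = overlap_series(maskT, xs, ys, x, y, sigma,
                                          truncSd);
  std::vector<double> pred = conv_causal(ov, hrf);
  const int n = obs.size();
  double sp = 0, so = 0, spp = 0, spo = 0;
  for (int t = 0; t < n; ++t) {
    sp += pred[t]; so += obs[t];
    spp += pred[t] * pred[t]; spo += pred[t] * obs[t];
  }
  const double mp = sp / n, mo = so / n;
  const double vp = spp - n * mp * mp;
  double beta = 0.0;
  if (vp > 1e-12) beta = (spo - n * mp * mo) / vp;
  const double alpha = mo - beta * mp;
  double sse = 0.0;
  for (int t = 0; t < n; ++t) {
    const double e = obs[t] - alpha - beta * pred[t];
    sse += e * e;
  }
  return sse;
}
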