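#include <Rcpp.h>
using namespace Rcpp;

// Kernel families: 0 uniform, 1 triangular, 2 gaussian, 3 epanechnikov.
// Weights are evaluated on u = offset / h with support |u| <= 1; the
// gaussian is truncated at the window edge (sigma in u-units).
static inline double kweight(double u, int family, double sigma) {
  double au = std::abs(u);
  if (au > 1.0) return 0.0;
  switch (family) {
  case 0: return 1.0;
  case 1: return 1.0 - au;
  case 2: return std::exp(-(u * u) / (2.0 * sigma * sigma));
  case 3: return 1.0 - u * u;
  default: stop("unknown kernel family code");
  }
  return 0.0;
}

// Weighted windowed sums of (m, n) around each evaluation position.
// posSrc must be sorted increasing; posEval sorted increasing.
// Returns weighted sums wm, wn, the total weight wsum and the number of
// source positions in the window. Normalisation is done by the caller.
// [[Rcpp::export(name = ".window_weighted_sums")]]
List window_weighted_sums(NumericVector posEval, NumericVector posSrc,
                          NumericVector m, NumericVector n,
                          double h, int family, double sigma) {
  R_xlen_t ne = posEval.size(), ns = posSrc.size();
  NumericVector wm(ne), wn(ne), wsum(ne);
  IntegerVector count(ne);
  R_xlen_t lo = 0, hi = 0; // window is posSrc in [pe - h, pe + h]
  for (R_xlen_t i = 0; i < ne; ++i) {
    double pe = posEval[i];
    while (lo < ns && posSrc[lo] < pe - h) ++lo;
    if (hi < lo) hi = lo;
    while (hi < ns && posSrc[hi] <= pe + h) ++hi;
    double sm = 0.0, sn = 0.0, sw = 0.0;
    int k = 0;
    for (R_xlen_t j = lo; j < hi; ++j) {
      double w = kweight((posSrc[j] - pe) / h, family, sigma);
      sm += w * m[j];
      sn += w * n[j];
      sw += w;
      ++k;
    }
    wm[i] = sm; wn[i] = sn; wsum[i] = sw; count[i] = k;
  }
  return List::create(_["wm"] = wm, _["wn"] = wn,
                      _["wsum"] = wsum, _["count"] = count);
}

// Plain windowed sums (uniform weights, no normalisation) used by the
// synthetic generator's moving-average latent process.
// [[Rcpp::export(name = ".window_sums")]]
List window_sums(NumericVector pos, NumericVector x, double h) {
  R_xlen_t ns = pos.size();
  NumericVector s(ns);
  IntegerVector k(ns);
  R_xlen_t lo = 0, hi = 0;
  for (R_xlen_t i = 0; i < ns; ++i) {
    double pe = pos[i];
    while (lo < ns && pos[lo] < pe - h) ++lo;
    if (hi < lo) hi = lo;
    while (hi < ns && pos[hi] <= pe + h) ++hi;
    double acc = 0.0;
    for (R_xlen_t j = lo; j < hi; ++j) acc += x[j];
    s[i] = acc; k[i] = (int)(hi - lo);
  }
  return List::create(_["sum"] = s, _["count"] = k);
}
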