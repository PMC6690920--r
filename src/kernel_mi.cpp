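#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Gaussian-kernel mutual information on the points indexed by idx (0-based).
// Product kernel with per-axis Silverman bandwidths h = 1.06 * sd * m^(-1/5);
// MI is the sample average of log( f(x,y) / (f1(x) f2(y)) ) at the observed
// points, clamped below at 0.  Densities are floored at 1e-300 before logs.
// sd uses the m-1 denominator to match R's sd().
static double mi_on_idx(const double *x, const double *y,
                        const int *idx, const int m,
                        std::vector<double> &ex, std::vector<double> &ey) {
  if (m < 2) return 0.0;
  double sx = 0, sy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < m; ++i) {
    const double xi = x[idx[i]], yi = y[idx[i]];
    sx += xi; sy += yi; sxx += xi * xi; syy += yi * yi;
  }
  const double mx = sx / m, my = sy / m;
  double vx = (sxx - m * mx * mx) / (m - 1);
  double vy = (syy - m * my * my) / (m - 1);
  if (vx <= 0.0 || vy <= 0.0) return 0.0; // degenerate subset: no dependency signal
  const double hx = 1.06 * std::sqrt(vx) * std::pow((double)m, -0.2);
  const double hy = 1.06 * std::sqrt(vy) * std::pow((double)m, -0.2);
  const double ax = -0.5 / (hx * hx), ay = -0.5 / (hy * hy);

  // symmetric kernel matrices, upper triangle computed once
  ex.resize((size_t)m * m);
  ey.resize((size_t)m * m);
  for (int i = 0; i < m; ++i) {
    const double xi = x[idx[i]], yi = y[idx[i]];
    ex[(size_t)i * m + i] = 1.0;
    ey[(size_t)i * m + i] = 1.0;
    for (int j = i + 1; j < m; ++j) {
      const double dx = xi - x[idx[j]];
      const double dy = yi - y[idx[j]];
      const double kx = std::exp(ax * dx * dx);
      const double ky = std::exp(ay * dy * dy);
      ex[(size_t)i * m + j] = kx; ex[(size_t)j * m + i] = kx;
      ey[(size_t)i * m + j] = ky; ey[(size_t)j * m + i] = ky;
    }
  }

  const double cst2 = 1.0 / std::sqrt(2.0 * M_PI);
  const double cx = cst2 / (m * hx);
  const double cy = cst2 / (m * hy);
  const double cxy = 1.0 / (2.0 * M_PI * m * hx * hy);
  double acc = 0.0;
  for (int i = 0; i < m; ++i) {
    const double *exi = &ex[(size_t)i * m];
    const double *eyi = &ey[(size_t)i * m];
    double fx = 0, fy = 0, fxy = 0;
    for (int j = 0; j < m; ++j) {
      fx += exi[j];
      fy += eyi[j];
      fxy += exi[j] * eyi[j];
    }
    fx *= cx; fy *= cy; fxy *= cxy;
    if (fx < 1e-300) fx = 1e-300;
    if (fy < 1e-300) fy = 1e-300;
    if (fxy < 1e-300) fxy = 1e-300;
    acc += std::log(fxy) - std::log(fx) - std::log(fy);
  }
  double mi = acc / m;
  return mi < 0.0 ? 0.0 : mi;
}

// [[Rcpp::export(name = ".kernel_mi_cpp")]]
double kernel_mi_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> ex, ey;
  return mi_on_idx(REAL(x), REAL(y), idx.data(), n, ex, ey);
}

// MI on one 1-based index subset.
// [[Rcpp::export(name = ".kernel_mi_subset_cpp")]]
double kernel_mi_subset_cpp(NumericVector x, NumericVector y, IntegerVector idx) {
  const int m = idx.size();
  std::vector<int> id(m);
  for (int i = 0; i < m; ++i) id[i] = idx[i] - 1;
  std::vector<double> ex, ey;
  return mi_on_idx(REAL(x), REAL(y), id.data(), m, ex, ey);
}

// CMI for many low/high splits at once: columns of low / high hold 1-based
// sample indices.  Returns mi_high - mi_low per column (each MI clamped at 0).
// [[Rcpp::export(name = ".cmi_splits_cpp")]]
NumericMatrix cmi_splits_cpp(NumericVector x, NumericVector y,
                             IntegerMatrix low, IntegerMatrix high) {
  const int r = low.ncol();
  if (high.ncol() != r) stop("low/high column mismatch");
  const int ml = low.nrow(), mh = high.nrow();
  NumericMatrix out(r, 3); // mi_low, mi_high, cmi
  std::vector<int> idl(ml), idh(mh);
  std::vector<double> ex, ey;
  for (int c = 0; c < r; ++c) {
    for (int i = 0; i < ml; ++i) idl[i] = low(i, c) - 1;
    for (int i = 0; i < mh; ++i) idh[i] = high(i, c) - 1;
    const double lo = mi_on_idx(REAL(x), REAL(y), idl.data(), ml, ex, ey);
    const double hi = mi_on_idx(REAL(x), REAL(y), idh.data(), mh, ex, ey);
    out(c, 0) = lo; out(c, 1) = hi; out(c, 2) = hi - lo;
  }
  return out;
}
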