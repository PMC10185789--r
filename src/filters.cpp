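#include <Rcpp.h>
using namespace Rcpp;

static void df2t(const std::vector<double>& bb, const std::vector<double>& aa,
                 const double* x, double* y, int n, int nz,
                 const double* zi) {
  // zi: steady-state unit-step initial state, scaled by the first sample so
  // the filter starts settled (suppresses the startup transient).
  std::vector<double> z(nz, 0.0);
  if (zi != nullptr && n > 0)
    for (int j = 0; j < nz; ++j) z[j] = zi[j] * x[0];
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
}

// Zero-phase (forward-backward) IIR filtering with odd-reflection padding
// of `pad` samples at both ends and steady-state initial conditions `zi`.
// [[Rcpp::export]]
NumericVector iir_filtfilt(NumericVector b, NumericVector a, NumericVector x,
                           int pad, NumericVector zi) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  const double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  if (pad > n - 1) pad = n - 1;
  if (pad < 0) pad = 0;
  const int m = n + 2 * pad;
  const double* zip = (zi.size() == nz) ? zi.begin() : nullptr;
  std::vector<double> xx(m), tmp(m);
  for (int i = 0; i < pad; ++i) xx[i] = 2.0 * x[0] - x[pad - i];
  for (int i = 0; i < n; ++i) xx[pad + i] = x[i];
  for (int i = 0; i < pad; ++i) xx[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  df2t(bb, aa, xx.data(), tmp.data(), m, nz, zip);
  std::reverse(tmp.begin(), tmp.end());
  df2t(bb, aa, tmp.data(), xx.data(), m, nz, zip);
  std::reverse(xx.begin(), xx.end());
  NumericVector y(n);
  for (int i = 0; i < n; ++i) y[i] = xx[pad + i];
  return y;
}

// Direct-form II transposed IIR filter, zero initial conditions.
// b, a: transfer-function coefficients (a[0] assumed 1 after normalisation).
// [[Rcpp::export]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0), z(nz, 0.0);
  const double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  NumericVector y(n);
  df2t(bb, aa, x.begin(), y.begin(), n, nz, nullptr);
  return y;
}
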