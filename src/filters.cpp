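#include <Rcpp.h>
using namespace Rcpp;

// One-pass IIR/FIR filter, direct form II transposed, zero initial state.
// b and a are pre-padded to common length m, a normalized so a[0] = 1.
// The biquad (m == 3) case keeps its state in scalars so the serial
// recursion stays in registers; cascaded second-order sections are the
// only hot path in practice.
static void filt_pass(const std::vector<double>& b,
                      const std::vector<double>& a,
                      std::vector<double>& x) {
  const size_t m = b.size(), n = x.size();
  if (m == 3) {
    const double b0 = b[0], b1 = b[1], b2 = b[2], a1 = a[1], a2 = a[2];
    double z1 = 0.0, z2 = 0.0;
    for (size_t t = 0; t < n; ++t) {
      const double xt = x[t];
      const double yt = b0 * xt + z1;
      z1 = b1 * xt - a1 * yt + z2;
      z2 = b2 * xt - a2 * yt;
      x[t] = yt;
    }
    return;
  }
  if (m == 2) {
    const double b0 = b[0], b1 = b[1], a1 = a[1];
    double z1 = 0.0;
    for (size_t t = 0; t < n; ++t) {
      const double xt = x[t];
      const double yt = b0 * xt + z1;
      z1 = b1 * xt - a1 * yt;
      x[t] = yt;
    }
    return;
  }
  std::vector<double> z(m, 0.0);
  for (size_t t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + z[0];
    for (size_t k = 1; k + 1 < m; ++k) {
      z[k - 1] = b[k] * xt - a[k] * yt + z[k];
    }
    z[m - 2] = b[m - 1] * xt - a[m - 1] * yt;
    x[t] = yt;
  }
}

// Zero-phase forward-backward filtering: append 2*max(nb, na) zeros,
// filter, reverse, filter, reverse, truncate to the original length
// (the convention of signal::filtfilt).
// [[Rcpp::export(name = ".filtfilt_cpp")]]
NumericVector filtfilt_cpp(NumericVector b, NumericVector a,
                           NumericVector x) {
  const size_t m = std::max(b.size(), a.size());
  std::vector<double> bb(m, 0.0), aa(m, 0.0);
  const double a0 = a[0];
  for (R_xlen_t k = 0; k < b.size(); ++k) bb[k] = b[k] / a0;
  for (R_xlen_t k = 0; k < a.size(); ++k) aa[k] = a[k] / a0;
  const size_t n = x.size();
  std::vector<double> y(x.begin(), x.end());
  y.resize(n + 2 * m, 0.0);
  filt_pass(bb, aa, y);
  std::reverse(y.begin(), y.end());
  filt_pass(bb, aa, y);
  std::reverse(y.begin(), y.end());
  NumericVector out(n);
  std::copy(y.begin(), y.begin() + n, out.begin());
  return out;
}
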