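#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with optional initial state.
// State convention matches the usual steady-state ("zi") initialization,
// so zero-phase wrappers can avoid start-up transients.
// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a, NumericVector x,
                             Nullable<NumericVector> zi = R_NilValue) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nf = std::max(na, nb);
  if (nf < 1 || a[0] == 0.0) stop("invalid filter coefficients");
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  std::vector<double> z(std::max(nf - 1, 1), 0.0);
  if (zi.isNotNull()) {
    NumericVector z0(zi);
    if (z0.size() != nf - 1) stop("zi must have length max(length(a), length(b)) - 1");
    for (int i = 0; i < nf - 1; ++i) z[i] = z0[i];
  }
  NumericVector y(n);
  const double *xp = x.begin();
  double *yp = y.begin();
  if (nf == 1) {  // pure gain
    for (int i = 0; i < n; ++i) yp[i] = bb[0] * xp[i];
    return y;
  }
  if (nf == 2) {  // first order (e.g. AR(1) backgrounds)
    const double b0 = bb[0], b1 = bb[1], a1 = aa[1];
    double z0 = z[0];
    for (int i = 0; i < n; ++i) {
      const double xi = xp[i];
      const double yi = b0 * xi + z0;
      z0 = b1 * xi - a1 * yi;
      yp[i] = yi;
    }
    return y;
  }
  if (nf == 3) {  // biquad (2nd-order low/high-pass sections)
    const double b0 = bb[0], b1 = bb[1], b2 = bb[2], a1 = aa[1], a2 = aa[2];
    double z0 = z[0], z1 = z[1];
    for (int i = 0; i < n; ++i) {
      const double xi = xp[i];
      const double yi = b0 * xi + z0;
      z0 = b1 * xi + z1 - a1 * yi;
      z1 = b2 * xi - a2 * yi;
      yp[i] = yi;
    }
    return y;
  }
  if (nf == 5) {  // 4th-order sections (butter(2) band-pass)
    const double b0 = bb[0], b1 = bb[1], b2 = bb[2], b3 = bb[3], b4 = bb[4];
    const double a1 = aa[1], a2 = aa[2], a3 = aa[3], a4 = aa[4];
    double z0 = z[0], z1 = z[1], z2 = z[2], z3 = z[3];
    for (int i = 0; i < n; ++i) {
      const double xi = xp[i];
      const double yi = b0 * xi + z0;
      z0 = b1 * xi + z1 - a1 * yi;
      z1 = b2 * xi + z2 - a2 * yi;
      z2 = b3 * xi + z3 - a3 * yi;
      z3 = b4 * xi - a4 * yi;
      yp[i] = yi;
    }
    return y;
  }
  if (nf == 9) {  // 8th-order polynomials (butter(4) band-pass, butter(8) low-pass)
    double B[9], A[9], Z[8];
    for (int j = 0; j < 9; ++j) { B[j] = bb[j]; A[j] = aa[j]; }
    for (int j = 0; j < 8; ++j) Z[j] = z[j];
    for (int i = 0; i < n; ++i) {
      const double xi = xp[i];
      const double yi = B[0] * xi + Z[0];
      Z[0] = B[1] * xi + Z[1] - A[1] * yi;
      Z[1] = B[2] * xi + Z[2] - A[2] * yi;
      Z[2] = B[3] * xi + Z[3] - A[3] * yi;
      Z[3] = B[4] * xi + Z[4] - A[4] * yi;
      Z[4] = B[5] * xi + Z[5] - A[5] * yi;
      Z[5] = B[6] * xi + Z[6] - A[6] * yi;
      Z[6] = B[7] * xi + Z[7] - A[7] * yi;
      Z[7] = B[8] * xi - A[8] * yi;
      yp[i] = yi;
    }
    return y;
  }
  for (int i = 0; i < n; ++i) {
    const double xi = xp[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 1; j < nf - 1; ++j) z[j - 1] = bb[j] * xi + z[j] - aa[j] * yi;
    z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    yp[i] = yi;
  }
  return y;
}

// Ordinal-pattern code per sliding window: the window x[i], x[i+tau], ...,
// x[i+(n-1)*tau] is reduced to the vector of 0-based ranks of its elements
// (stable: equal amplitudes rank by earlier index first) and encoded as
// sum_j rank_j * n^j. Codes are decoded to sorting permutations in R.
// [[Rcpp::export]]
IntegerVector cpp_ordinal_codes(NumericVector x, int n, int tau) {
  const int len = x.size();
  const int L = len - (n - 1) * tau;
  if (n < 2 || tau < 1) stop("need n >= 2 and tau >= 1");
  if (L < 1) stop("signal too short for the requested embedding");
  IntegerVector codes(L);
  std::vector<int> npow(n);
  npow[0] = 1;
  for (int j = 1; j < n; ++j) npow[j] = npow[j - 1] * n;
  for (int i = 0; i < L; ++i) {
    int code = 0;
    for (int j = 0; j < n; ++j) {
      const double xj = x[i + j * tau];
      int r = 0;
      for (int k = 0; k < n; ++k) {
        if (k == j) continue;
        const double xk = x[i + k * tau];
        if (xk < xj || (xk == xj && k < j)) ++r;
      }
      code += r * npow[j];
    }
    codes[i] = code;
  }
  return codes;
}
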