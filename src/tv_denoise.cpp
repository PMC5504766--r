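#include <Rcpp.h>
using namespace Rcpp;

// Exact 1-D total-variation denoising: the unique minimizer of
//   0.5 * sum_t (x_t - y_t)^2 + lam * sum_t |x_{t+1} - x_t|
// via Condat's direct algorithm.  Non-iterative and exact up to floating
// point; O(N) typical.  Indices 0-based; k0 marks the start of the segment
// currently being built, km/kp the last position where the running lower /
// upper tube bound was saturated.
static void tv1d_condat(const double *y, double *x, const int N,
                        const double lam) {
  if (N == 1 || lam <= 0.0) {
    for (int i = 0; i < N; ++i) x[i] = y[i];
    return;
  }
  int k = 0, k0 = 0, km = 0, kp = 0;
  double vmin = y[0] - lam, vmax = y[0] + lam;
  double umin = lam, umax = -lam;
  for (;;) {
    while (k == N - 1) { /* end of signal: flush trailing segments */
      if (umin < 0.0) {
        for (int i = k0; i <= km; ++i) x[i] = vmin;
        k = k0 = km = km + 1;
        vmin = y[k];
        umin = lam;
        umax = y[k] + lam - vmax;
      } else if (umax > 0.0) {
        for (int i = k0; i <= kp; ++i) x[i] = vmax;
        k = k0 = kp = kp + 1;
        vmax = y[k];
        umax = -lam;
        umin = y[k] - lam - vmin;
      } else {
        const double v = vmin + umin / (k - k0 + 1);
        for (int i = k0; i < N; ++i) x[i] = v;
        return;
      }
    }
    if (y[k + 1] + umin < vmin - lam) { /* negative jump: emit min segment */
      for (int i = k0; i <= km; ++i) x[i] = vmin;
      k = k0 = km = kp = km + 1;
      vmin = y[k];
      vmax = y[k] + 2.0 * lam;
      umin = lam;
      umax = -lam;
    } else if (y[k + 1] + umax > vmax + lam) { /* positive jump */
      for (int i = k0; i <= kp; ++i) x[i] = vmax;
      k = k0 = km = kp = kp + 1;
      vmin = y[k] - 2.0 * lam;
      vmax = y[k];
      umin = lam;
      umax = -lam;
    } else { /* no jump: extend the current segment */
      ++k;
      umin += y[k] - vmin;
      umax += y[k] - vmax;
      if (umin >= lam) {
        vmin += (umin - lam) / (k - k0 + 1);
        umin = lam;
        km = k;
      }
      if (umax <= -lam) {
        vmax += (umax + lam) / (k - k0 + 1);
        umax = -lam;
        kp = k;
      }
    }
  }
}

// [[Rcpp::export(name = ".tv1d")]]
NumericVector tv1d(NumericVector y, double lam) {
  const int n = y.size();
  NumericVector out(n);
  tv1d_condat(y.begin(), out.begin(), n, lam);
  return out;
}

// Row-wise TV denoising of a matrix (each row smoothed independently).
// [[Rcpp::export(name = ".tv1d_rows")]]
NumericMatrix tv1d_rows(NumericMatrix x, double lam) {
  const int p = x.nrow(), n = x.ncol();
  NumericMatrix out(p, n);
  std::vector<double> row(n), res(n);
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < n; ++j) row[j] = x(i, j);
    tv1d_condat(row.data(), res.data(), n, lam);
    for (int j = 0; j < n; ++j) out(i, j) = res[j];
  }
  return out;
}
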