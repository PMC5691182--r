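#include <Rcpp.h>
using namespace Rcpp;

// Thomas algorithm for a tridiagonal system.
// lower: subdiagonal (n-1), diag: main diagonal (n), upper: superdiagonal
// (n-1), rhs: right-hand side (n). No pivoting: the implicit-Euler systems
// solved here are strictly diagonally dominant for admissible time steps.
// [[Rcpp::export]]
NumericVector thomas_solve(NumericVector lower, NumericVector diag,
                           NumericVector upper, NumericVector rhs) {
  int n = diag.size();
  if (n == 1) return NumericVector::create(rhs[0] / diag[0]);
  NumericVector cp(n - 1), dp(n), x(n);
  cp[0] = upper[0] / diag[0];
  dp[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    double m = diag[i] - lower[i - 1] * cp[i - 1];
    if (i < n - 1) cp[i] = upper[i] / m;
    dp[i] = (rhs[i] - lower[i - 1] * dp[i - 1]) / m;
  }
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
  return x;
}
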