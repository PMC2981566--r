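#include <Rcpp.h>
using namespace Rcpp;

// Simulate a discrete-time state-space system
//   x[k+1] = Ad x[k] + Bd u[k]
//   y[k]   = C  x[k] + D  u[k]
// with zero initial state. C is (m x n), D length m; returns a (T x m) matrix
// of outputs. This is the inner loop of every block-model simulation, so it is
// compiled; everything else stays in R.
// [[Rcpp::export]]
NumericMatrix dss_sim(const NumericMatrix& Ad, const NumericVector& Bd,
                      const NumericMatrix& C, const NumericVector& D,
                      const NumericVector& u) {
  const int n = Ad.nrow(), m = C.nrow(), T = u.size();
  if (Ad.ncol() != n || Bd.size() != n || C.ncol() != n || D.size() != m)
    stop("inconsistent state-space dimensions");
  NumericMatrix y(T, m);
  std::vector<double> x(n, 0.0), xn(n);
  for (int k = 0; k < T; ++k) {
    const double uk = u[k];
    for (int i = 0; i < m; ++i) {
      double acc = D[i] * uk;
      for (int j = 0; j < n; ++j) acc += C(i, j) * x[j];
      y(k, i) = acc;
    }
    for (int i = 0; i < n; ++i) {
      double acc = Bd[i] * uk;
      for (int j = 0; j < n; ++j) acc += Ad(i, j) * x[j];
      xn[i] = acc;
    }
    x.swap(xn);
  }
  return y;
}
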