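#include <Rcpp.h>
using namespace Rcpp;

// Weighted L1 (Manhattan) cross-distance matrix between the rows of A and the
// rows of B: out[i, j] = sum_d w[d] * |A(i, d) - B(j, d)|.  Features with zero
// weight contribute nothing but are kept in the loop bound so that index
// bookkeeping matches the R side.
// [[Rcpp::export(name = ".wl1_cross_cpp")]]
NumericMatrix wl1_cross_cpp(NumericMatrix A, NumericMatrix B, NumericVector w) {
  const int n = A.nrow(), m = B.nrow(), D = A.ncol();
  if (B.ncol() != D || w.size() != D)
    stop("dimension mismatch in weighted L1 cross-distance");
  NumericMatrix out(n, m);
  double *po = out.begin();
  const double *pa = A.begin(), *pb = B.begin();
  for (int d = 0; d < D; ++d) {
    const double wd = w[d];
    if (wd == 0.0) continue;
    const double *ad = pa + (size_t)d * n;
    const double *bd = pb + (size_t)d * m;
    for (int j = 0; j < m; ++j) {
      const double b = bd[j];
      double *oj = po + (size_t)j * n;
      for (int i = 0; i < n; ++i) {
        oj[i] += wd * std::abs(ad[i] - b);
      }
    }
  }
  return out;
}

// Weighted L1 distances from one point x to each row of A.
// [[Rcpp::export(name = ".wl1_to_point_cpp")]]
NumericVector wl1_to_point_cpp(NumericMatrix A, NumericVector x, NumericVector w) {
  const int n = A.nrow(), D = A.ncol();
  if (x.size() != D || w.size() != D)
    stop("dimension mismatch in weighted L1 point distance");
  NumericVector out(n);
  double *po = out.begin();
  const double *pa = A.begin();
  for (int d = 0; d < D; ++d) {
    const double wd = w[d];
    if (wd == 0.0) continue;
    const double xd = x[d];
    const double *ad = pa + (size_t)d * n;
    for (int i = 0; i < n; ++i) {
      po[i] += wd * std::abs(ad[i] - xd);
    }
  }
  return out;
}
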