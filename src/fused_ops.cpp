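#include <Rcpp.h>
using namespace Rcpp;

// Fused per-column affine: out[i,j] = Z[i,j] * a[j] + b[j].
// Used by the batch-norm layers to avoid building broadcast matrices.
// [[Rcpp::export]]
NumericMatrix colscale_add(const NumericMatrix& Z, const NumericVector& a,
                           const NumericVector& b) {
  const R_xlen_t n = Z.nrow(), m = Z.ncol();
  NumericMatrix out(n, m);
  for (R_xlen_t j = 0; j < m; ++j) {
    const double aj = a[j], bj = b[j];
    const double* zi = &Z(0, j);
    double* oi = &out(0, j);
    for (R_xlen_t i = 0; i < n; ++i) oi[i] = zi[i] * aj + bj;
  }
  return out;
}

// Fused per-column combination of two matrices: X[i,j]*a[j] + Y[i,j]*q[j] + r[j].
// The batch-norm backward pass collapses to this form.
// [[Rcpp::export]]
NumericMatrix colscale_two(const NumericMatrix& X, const NumericMatrix& Y,
                           const NumericVector& a, const NumericVector& q,
                           const NumericVector& r) {
  const R_xlen_t n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, m);
  for (R_xlen_t j = 0; j < m; ++j) {
    const double aj = a[j], qj = q[j], rj = r[j];
    const double* xi = &X(0, j);
    const double* yi = &Y(0, j);
    double* oi = &out(0, j);
    for (R_xlen_t i = 0; i < n; ++i) oi[i] = xi[i] * aj + yi[i] * qj + rj;
  }
  return out;
}

// colSums(X * Y) without materialising the product.
// [[Rcpp::export]]
NumericVector cross_colsums(const NumericMatrix& X, const NumericMatrix& Y) {
  const R_xlen_t n = X.nrow(), m = X.ncol();
  NumericVector out(m);
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* xi = &X(0, j);
    const double* yi = &Y(0, j);
    double s = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) s += xi[i] * yi[i];
    out[j] = s;
  }
  return out;
}
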