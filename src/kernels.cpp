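#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update of one parameter leaf. p, m and v are owned by the
// optimizer state (never aliased by checkpoints, which are deep copies), so
// mutating them in place is safe and avoids reallocating ~11M doubles per
// step.
// [[Rcpp::export]]
void adam_update_leaf(NumericVector p, NumericVector m, NumericVector v,
                      NumericVector g, double lr, double bc1, double bc2,
                      double beta1, double beta2, double eps) {
  R_xlen_t n = p.size();
  double *pp = REAL(p), *pm = REAL(m), *pv = REAL(v), *pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = beta1 * pm[i] + (1.0 - beta1) * pg[i];
    pv[i] = beta2 * pv[i] + (1.0 - beta2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / bc1) / (std::sqrt(pv[i] / bc2) + eps);
  }
}

// target[idx[i]] += vals[i] with 1-based indices and accumulation across
// duplicates (the col2im step of the convolution backward pass).
// [[Rcpp::export]]
void scatter_add(NumericVector target, IntegerVector idx, NumericVector vals) {
  R_xlen_t n = idx.size();
  if (vals.size() != n) stop("idx and vals must have equal length");
  double *pt = REAL(target), *pv = REAL(vals);
  int *pi = INTEGER(idx);
  R_xlen_t tn = target.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int j = pi[i] - 1;
    if (j < 0 || j >= tn) stop("scatter index out of range");
    pt[j] += pv[i];
  }
}
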