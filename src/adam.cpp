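#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place Adam update for one parameter tensor. The caller owns p,
// m and v exclusively (they are duplicated once at the start of training),
// so in-place mutation is safe and avoids ~10 full-tensor temporaries per
// step that a vectorised R implementation would allocate.
//
// p <- p - lr * mhat / (sqrt(vhat) + eps), with
// m <- b1 m + (1-b1) g;  v <- b2 v + (1-b2) g^2;
// mhat = m / (1 - b1^t); vhat = v / (1 - b2^t).
// [[Rcpp::export(name = ".adam_step")]]
void adam_step(NumericVector p, NumericVector m, NumericVector v,
               NumericVector g, double lr, double b1, double b2,
               double eps, double bc1, double bc2) {
  const R_xlen_t n = p.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam_step: length mismatch");
  const double s2 = std::sqrt(bc2);      // sqrt(1 - b2^t)
  const double a = lr * s2 / bc1;        // folds both bias corrections
  double *pp = REAL(p), *pm = REAL(m), *pv = REAL(v), *pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = pg[i];
    pm[i] = b1 * pm[i] + (1.0 - b1) * gi;
    pv[i] = b2 * pv[i] + (1.0 - b2) * gi * gi;
    pp[i] -= a * pm[i] / (std::sqrt(pv[i]) + eps * s2);
  }
}
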