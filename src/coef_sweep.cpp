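#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sweep over the columns of X with running-residual
// bookkeeping.  `r` holds y_latent minus the full linear predictor and is
// updated in place together with the coefficient vector `b`; both must be
// buffers owned exclusively by the caller.  pvar[j] is the prior variance
// of b[j] (tau2_j * sigma2_e for markers, sigma2_u for pedigree columns).
// Columns with zero sum of squares (monomorphic after centering) or zero
// prior variance keep b[j] = 0 and are skipped.  Uses R's RNG so draws are
// reproducible from set.seed().
// [[Rcpp::export(name = ".gibbs_coef_sweep")]]
void gibbs_coef_sweep(NumericMatrix X, NumericVector r, NumericVector b,
                      NumericVector xtx, NumericVector pvar, double sigma2e) {
  const int n = X.nrow(), p = X.ncol();
  if (r.size() != n || b.size() != p || xtx.size() != p || pvar.size() != p)
    stop("dimension mismatch in coefficient sweep");
  const double* xbase = REAL(X);
  double* __restrict__ rp = REAL(r);
  double* bp = REAL(b);
  const double* xtxp = REAL(xtx);
  const double* pvp = REAL(pvar);
  for (int j = 0; j < p; ++j) {
    const double* __restrict__ xj = xbase + (size_t)n * j;
    if (xtxp[j] <= 0.0 || pvp[j] <= 0.0) {
      if (bp[j] != 0.0) {
        const double bj = bp[j];
        for (int i = 0; i < n; ++i) rp[i] += xj[i] * bj;
        bp[j] = 0.0;
      }
      continue;
    }
    double cj = 0.0;
    for (int i = 0; i < n; ++i) cj += xj[i] * rp[i];
    cj += xtxp[j] * bp[j];
    const double Cj = xtxp[j] + sigma2e / pvp[j];
    const double bnew = ::Rf_rnorm(cj / Cj, std::sqrt(sigma2e / Cj));
    const double d = bnew - bp[j];
    if (d != 0.0) for (int i = 0; i < n; ++i) rp[i] -= xj[i] * d;
    bp[j] = bnew;
  }
}
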