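#include <Rcpp.h>
using namespace Rcpp;

// One full coordinate pass over the (b_k, s_k) spike-and-slab pairs of a
// node regression.  The residual vector r = y - Z %*% (alpha * mu) is
// maintained incrementally so each coefficient update costs O(n).
//
// e_tau / elog_tau / elogit_pi are per-coefficient expectations under the
// current hyper-posteriors: E[tau_l(k)], E[log tau_l(k)] and
// E[log pi_k] - E[log(1 - pi_k)].
//
// [[Rcpp::export(name = ".caviCoefPass")]]
List cavi_coef_pass(const NumericMatrix& Z,
                    const NumericVector& ztz,
                    const NumericVector& alpha_,
                    const NumericVector& mu_,
                    const NumericVector& sigma2_,
                    const NumericVector& resid_,
                    const double e_omega,
                    const NumericVector& e_tau,
                    const NumericVector& elog_tau,
                    const NumericVector& elogit_pi) {
  NumericVector alpha = clone(alpha_);
  NumericVector mu = clone(mu_);
  NumericVector sigma2 = clone(sigma2_);
  NumericVector r = clone(resid_);
  const int n = Z.nrow();
  const int m = Z.ncol();

  for (int k = 0; k < m; ++k) {
    const double old_b = alpha[k] * mu[k];
    // z_k' (r + z_k * old_b): partial residual with coefficient k removed
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += Z(i, k) * r[i];
    dot += ztz[k] * old_b;

    const double s2 = 1.0 / (e_omega * ztz[k] + e_tau[k]);
    const double m1 = s2 * e_omega * dot;
    const double logit = elogit_pi[k] + 0.5 * (elog_tau[k] + std::log(s2)) +
                         0.5 * m1 * m1 / s2;
    if (!std::isfinite(m1) || !std::isfinite(logit))
      stop("non-finite coefficient update at index %d", k + 1);
    double a;
    if (logit > 0.0) {
      a = 1.0 / (1.0 + std::exp(-logit));
    } else {
      const double e = std::exp(logit);
      a = e / (1.0 + e);
    }

    const double diff = old_b - a * m1;
    if (diff != 0.0)
      for (int i = 0; i < n; ++i) r[i] += Z(i, k) * diff;
    alpha[k] = a;
    mu[k] = m1;
    sigma2[k] = s2;
  }

  return List::create(_["alpha"] = alpha, _["mu"] = mu,
                      _["sigma2"] = sigma2, _["resid"] = r);
}
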