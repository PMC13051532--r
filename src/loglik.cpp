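#include <Rcpp.h>
using namespace Rcpp;

// Marginal log-likelihood kernel for the Weibull AFT illness-death model.
//
// Log-survival is evaluated in log space,
//   log S(t) = -exp(kappa * (log t - lp)),   lp = x'beta + u,
// and the quadrature mixture over random-effect nodes via log-sum-exp.
// For speed the node-independent factor exp(kappa * (log t - x'beta)) is
// precomputed per subject and the node factor exp(-kappa * u_q) per node,
// so the inner loop is mostly multiplications.
//
// tr and trunc1 must be 0 for undiagnosed subjects (unused there); trunc1
// is the truncation age of the post-diagnosis death submodel (interval
// midpoint capped at the last observed age by the caller).

// [[Rcpp::export]]
NumericVector idm_loglik_cpp(NumericVector L, NumericVector tl,
                             NumericVector tr, NumericVector trunc1,
                             NumericVector y2, IntegerVector d1,
                             IntegerVector d2, NumericMatrix X,
                             NumericMatrix beta, NumericVector kappa,
                             NumericMatrix U, NumericVector w) {
  const int n = L.size();
  const int d = X.ncol();
  const int Q = U.nrow();
  NumericVector out(n);

  const double ki = kappa[0], k0 = kappa[1], k1 = kappa[2];

  // node factors exp(-kappa_p * u_qp) and their logs, shared by all subjects
  std::vector<double> ei(Q), e0(Q), e1(Q), ku1(Q), ku0(Q), logw(Q);
  for (int q = 0; q < Q; ++q) {
    ei[q] = std::exp(-ki * U(q, 0));
    e0[q] = std::exp(-k0 * U(q, 1));
    e1[q] = std::exp(-k1 * U(q, 2));
    ku0[q] = -k0 * U(q, 1);       // additive part of log f_m0 at a node
    ku1[q] = -k1 * U(q, 2);
    logw[q] = std::log(w[q]);
  }

  std::vector<double> lq(Q);
  const double log_ki = std::log(ki), log_k0 = std::log(k0),
               log_k1 = std::log(k1);
  (void)log_ki;

  for (int j = 0; j < n; ++j) {
    double xb_i = 0.0, xb_0 = 0.0, xb_1 = 0.0;
    for (int c = 0; c < d; ++c) {
      const double x = X(j, c);
      xb_i += x * beta(c, 0);
      xb_0 += x * beta(c, 1);
      xb_1 += x * beta(c, 2);
    }
    // subject-level bases a = exp(kappa*(log t - x'beta)); log S = -a * e_q
    const double logL = (L[j] > 0.0) ? std::log(L[j]) : R_NegInf;
    const double a_iL = (L[j] > 0.0) ? std::exp(ki * (logL - xb_i)) : 0.0;
    const double a_0L = (L[j] > 0.0) ? std::exp(k0 * (logL - xb_0)) : 0.0;
    const double logy = std::log(y2[j]);

    double a_itl = 0, a_itr = 0, a_0tr = 0, a_1tm = 0, a_1y = 0, c_f1 = 0,
           a_iy = 0, a_0y = 0, c_f0 = 0;
    if (d1[j] == 1) {
      a_itl = (tl[j] > 0.0) ? std::exp(ki * (std::log(tl[j]) - xb_i)) : 0.0;
      a_itr = std::exp(ki * (std::log(tr[j]) - xb_i));
      a_0tr = std::exp(k0 * (std::log(tr[j]) - xb_0));
      a_1tm = std::exp(k1 * (std::log(trunc1[j]) - xb_1));
      a_1y  = std::exp(k1 * (logy - xb_1));
      // node-independent part of log f_m1(y2)
      c_f1 = log_k1 + (k1 - 1.0) * logy - k1 * xb_1;
    } else {
      a_iy = std::exp(ki * (logy - xb_i));
      a_0y = std::exp(k0 * (logy - xb_0));
      c_f0 = log_k0 + (k0 - 1.0) * logy - k0 * xb_0;
    }

    double m = R_NegInf;
    for (int q = 0; q < Q; ++q) {
      double ll = a_iL * ei[q] + a_0L * e0[q];   // minus log truncation prob
      if (d1[j] == 1) {
        const double sl = -a_itl * ei[q];
        const double sr = -a_itr * ei[q];
        const double dlt = sr - sl;
        const double intv = (dlt < 0.0) ? sl + std::log1p(-std::exp(dlt))
                                        : R_NegInf;
        ll += intv - a_0tr * e0[q] + a_1tm * e1[q];
        ll += (d2[j] == 1) ? (c_f1 + ku1[q] - a_1y * e1[q])
                           : (-a_1y * e1[q]);
      } else {
        ll += -a_iy * ei[q];
        ll += (d2[j] == 1) ? (c_f0 + ku0[q] - a_0y * e0[q])
                           : (-a_0y * e0[q]);
      }
      lq[q] = ll + logw[q];
      if (lq[q] > m) m = lq[q];
    }
    if (!std::isfinite(m)) {
      out[j] = m;
    } else {
      double s = 0.0;
      for (int q = 0; q < Q; ++q) s += std::exp(lq[q] - m);
      out[j] = m + std::log(s);
    }
  }
  return out;
}
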