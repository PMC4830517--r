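#include <Rcpp.h>
using namespace Rcpp;

// Per-subject marginal log-likelihood of the joint model.
//
// The longitudinal factor has already been integrated analytically in R
// (the marginal Gaussian log-likelihood Clong and the exact posterior
// b | y ~ N(mu_i, Sigma_i) at the current parameters); what remains is the
// posterior expectation of the survival factor
//   g_i(b) = delta_i log h_i(T_i; b) - Lambda_i(T_i; b),
// computed by Gauss-Hermite quadrature with nodes mapped through the
// posterior (B0, B1) and plain weights logwt (no Jacobian or e^{|z|^2}
// inflation: the Gaussian is handled exactly).
//
//   v      (N x Q): outer quadrature weights, scaled by T_i/2
//   loghq  (N x Q): log h0 at the outer nodes (current spline coefs)
//   loghT  (N):     log h0 at T_i
//   A0q/A1q (N x Q), A0T/A1T (N): association-feature coefficients merged
//       with alpha, so the feature offset is a*A0 + c*A1 for a trajectory
//       a + c s (a = beta0 + b0, c = beta1 + b1)
//   gw     (N): gamma' w_i
//
// Returns the N-vector Clong_i + log E[ exp(g_i(b)) | y_i ].
// [[Rcpp::export]]
NumericVector joint_subject_loglik_cpp(double beta0, double beta1,
                                       NumericVector Clong,
                                       NumericVector delta,
                                       NumericVector gw,
                                       NumericMatrix v,
                                       NumericMatrix loghq,
                                       NumericVector loghT,
                                       NumericMatrix A0q, NumericMatrix A1q,
                                       NumericVector A0T, NumericVector A1T,
                                       NumericMatrix B0, NumericMatrix B1,
                                       NumericVector logwt) {
  const int N = v.nrow();
  const int Q = v.ncol();
  const int M = B0.ncol();

  NumericVector out(N);
  std::vector<double> terms(M);
  for (int i = 0; i < N; ++i) {
    double mx = R_NegInf;
    for (int k = 0; k < M; ++k) {
      const double a = beta0 + B0(i, k), c = beta1 + B1(i, k);
      double Lam = 0.0;
      for (int q = 0; q < Q; ++q) {
        Lam += v(i, q) *
               std::exp(loghq(i, q) + gw[i] + a * A0q(i, q) + c * A1q(i, q));
      }
      double g = -Lam;
      if (delta[i] > 0.5)
        g += loghT[i] + gw[i] + a * A0T[i] + c * A1T[i];
      const double term = logwt[k] + g;
      terms[k] = term;
      if (term > mx) mx = term;
    }
    if (!std::isfinite(mx)) { out[i] = R_NegInf; continue; }
    double s = 0.0;
    for (int k = 0; k < M; ++k) s += std::exp(terms[k] - mx);
    out[i] = Clong[i] + mx + std::log(s);
  }
  return out;
}
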