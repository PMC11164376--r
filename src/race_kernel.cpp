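#include <Rcpp.h>
using namespace Rcpp;

// Inverse-Gaussian (Wald) first-passage density of a unit-diffusion Wiener
// process with drift mu > 0 and absorbing boundary b > 0, in log form.
static inline double log_ig_pdf(double t, double mu, double b) {
  double d = b - mu * t;
  return std::log(b) - 0.5 * (std::log(2.0 * M_PI) + 3.0 * std::log(t)) -
         d * d / (2.0 * t);
}

// log survival S(t) = P(T > t) = Phi(-z1) - exp(2 mu b) Phi(z2),
// z1 = (mu t - b)/sqrt(t), z2 = -(mu t + b)/sqrt(t).
// Both terms are computed in log space; the second can overflow naively
// when 2 mu b is large, but 2 mu b + log Phi(z2) is always <= log Phi(-z1).
static inline double log_ig_sf(double t, double mu, double b) {
  double st = std::sqrt(t);
  double la = R::pnorm((b - mu * t) / st, 0.0, 1.0, 1, 1);
  double lb = 2.0 * mu * b + R::pnorm(-(mu * t + b) / st, 0.0, 1.0, 1, 1);
  if (lb >= la) return R_NegInf;
  return la + std::log1p(-std::exp(lb - la));
}

// Per-trial log-likelihood of the independent four-accumulator race:
// the chosen accumulator contributes its first-passage density at the
// decision time, every other accumulator its survival probability.
// dt is the decision time (observed RT minus the non-decision offset);
// non-positive dt yields -Inf rather than an error so that Metropolis
// proposals that violate the offset constraint are simply rejected.
// [[Rcpp::export]]
NumericVector race_ll_rows(NumericMatrix mu, NumericMatrix b,
                           NumericVector dt, IntegerVector resp) {
  int n = dt.size(), K = mu.ncol();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    double t = dt[r];
    if (!(t > 0.0)) { out[r] = R_NegInf; continue; }
    int d = resp[r] - 1;
    double ll = log_ig_pdf(t, mu(r, d), b(r, d));
    for (int k = 0; k < K; ++k) {
      if (k == d) continue;
      ll += log_ig_sf(t, mu(r, k), b(r, k));
      if (ll == R_NegInf) break;
    }
    out[r] = ll;
  }
  return out;
}
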