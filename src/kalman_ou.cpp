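#include <Rcpp.h>
using namespace Rcpp;

// Exact marginal log-likelihood of a stationary OU process with diffusivity D
// (stationary variance D*tau) and correlation time tau around an unknown
// constant level, observed through additive white Gaussian measurement noise
// of standard deviation meas_sd at uniform sampling. The level is a diffuse
// Kalman state (prior variance `diffuse` times the data variance), which
// avoids the small-sample bias that subtracting the sample mean induces in
// tau. NA observations are treated as missing (time update only), encoding
// illumination gaps. Two-state time-varying Kalman filter.
// [[Rcpp::export]]
double ou_kalman_loglik(NumericVector y, double dt, double D, double tau,
                        double meas_sd, double diffuse = 1e6) {
  if (D < 0 || tau <= 0 || dt <= 0) return R_NegInf;
  const double phi = std::exp(-dt / tau);
  const double svar = D * tau;
  const double q = svar * (1.0 - phi * phi);
  const double r = meas_sd * meas_sd;
  const double LOG2PI = 1.8378770664093453;
  int n = y.size();
  // data variance for the diffuse-level scale (NA-safe)
  double s1 = 0, s2 = 0; int nobs = 0;
  for (int i = 0; i < n; ++i)
    if (!NumericVector::is_na(y[i])) { s1 += y[i]; s2 += y[i] * y[i]; ++nobs; }
  if (nobs < 3) return R_NegInf;
  double vy = std::max(s2 / nobs - (s1 / nobs) * (s1 / nobs), 1e-300);
  // state (eta, mu); eta stationary OU, mu constant with diffuse prior
  double m0 = 0.0, m1 = s1 / nobs;
  double P00 = svar, P01 = 0.0, P11 = diffuse * vy;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!NumericVector::is_na(y[i])) {
      double S = P00 + 2.0 * P01 + P11 + r;
      double e = y[i] - (m0 + m1);
      ll += -0.5 * (LOG2PI + std::log(S) + e * e / S);
      double K0 = (P00 + P01) / S;
      double K1 = (P01 + P11) / S;
      m0 += K0 * e;
      m1 += K1 * e;
      double n00 = P00 - K0 * (P00 + P01);
      double n01 = P01 - K0 * (P01 + P11);
      double n11 = P11 - K1 * (P01 + P11);
      P00 = n00; P01 = n01; P11 = n11;
    }
    // time update: eta <- phi * eta + noise, mu constant
    m0 = phi * m0;
    P00 = phi * phi * P00 + q;
    P01 = phi * P01;
  }
  return ll;
}
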