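#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-branch binary hierarchical Gaussian filter.
//
// Runs the full trial-by-trial variational update for a sequence of binary
// inputs. Level 1 is the binary observation (advice accurate / card blue),
// level 2 the latent tendency, level 3 the log-volatility of that tendency.
// When update_level3 is false the volatility state is frozen at its initial
// value (two-level filter); theta is then only used for the exported
// predicted level-3 precision.
//
// Returns trial-wise predictions (hatted quantities), posteriors, prediction
// errors and precision-weighted prediction errors. If the level-3 precision
// update turns non-positive (filter divergence) the integer `diverged_at`
// carries the 1-based trial index and the trajectories are truncated there.
// [[Rcpp::export]]
List hgf_binary_filter_cpp(NumericVector u,
                           double kappa,
                           double theta,
                           double omega,
                           double mu2_0,
                           double sigma2_0,
                           double mu3_0,
                           double sigma3_0,
                           bool update_level3,
                           double precision_floor) {
  const int T = u.size();
  NumericVector muhat1(T), pihat1(T), delta1(T),
      muhat2(T), pihat2(T), pi2(T), mu2(T), eps2(T),
      delta2(T), muhat3(T), pihat3(T), pi3(T), mu3(T), eps3(T);
  int diverged_at = 0;
  bool floored = false;

  double mu2p = mu2_0, pi2p = 1.0 / sigma2_0;
  double mu3p = mu3_0, pi3p = 1.0 / sigma3_0;

  for (int k = 0; k < T; ++k) {
    // level 1: prediction from previous level-2 mean
    const double mh2 = mu2p;
    const double mh1 = 1.0 / (1.0 + std::exp(-mh2));
    const double s1 = mh1 * (1.0 - mh1);     // 1 / pihat1
    const double d1 = u[k] - mh1;

    // level 2
    const double v2 = std::exp(kappa * mu3p + omega);
    double ph2 = 1.0 / (1.0 / pi2p + v2);
    if (ph2 < precision_floor) { ph2 = precision_floor; floored = true; }
    const double p2 = ph2 + s1;              // pi2 = pihat2 + muhat1(1-muhat1)
    const double m2 = mh2 + d1 / p2;
    const double e2 = d1 / p2;

    // volatility prediction error
    const double dm2 = m2 - mh2;
    const double d2 = (1.0 / p2 + dm2 * dm2) * ph2 - 1.0;

    // level 3
    const double mh3 = mu3p;
    double ph3 = 1.0 / (1.0 / pi3p + theta);
    if (ph3 < precision_floor) { ph3 = precision_floor; floored = true; }
    double p3, m3;
    if (update_level3) {
      const double w2 = v2 * ph2;
      p3 = ph3 + 0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * d2);
      if (!(p3 > 0.0) || !std::isfinite(p3)) {
        diverged_at = k + 1;
        break;
      }
      m3 = mh3 + 0.5 * kappa * (w2 / p3) * d2;
    } else {
      p3 = pi3p;
      m3 = mu3p;
    }
    const double e3 = d2 / p3;

    if (!std::isfinite(m2) || !std::isfinite(p2) || !std::isfinite(m3)) {
      diverged_at = k + 1;
      break;
    }

    muhat1[k] = mh1; pihat1[k] = 1.0 / s1; delta1[k] = d1;
    muhat2[k] = mh2; pihat2[k] = ph2; pi2[k] = p2; mu2[k] = m2; eps2[k] = e2;
    delta2[k] = d2; muhat3[k] = mh3; pihat3[k] = ph3; pi3[k] = p3; mu3[k] = m3;
    eps3[k] = e3;

    mu2p = m2; pi2p = p2; mu3p = m3; pi3p = p3;
  }

  return List::create(
      _["muhat1"] = muhat1, _["pihat1"] = pihat1, _["delta1"] = delta1,
      _["muhat2"] = muhat2, _["pihat2"] = pihat2, _["pi2"] = pi2,
      _["mu2"] = mu2, _["eps2"] = eps2, _["delta2"] = delta2,
      _["muhat3"] = muhat3, _["pihat3"] = pihat3, _["pi3"] = pi3,
      _["mu3"] = mu3, _["eps3"] = eps3,
      _["diverged_at"] = diverged_at, _["floored"] = floored);
}
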