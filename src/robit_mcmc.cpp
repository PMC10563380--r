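#include <Rcpp.h>
using namespace Rcpp;

// Log-posterior of the robit efficacy model on the transformed scale.
// Parameters (length 7): alpha, b1, b2, g1, g2, log(v), u where
// df = adf + (bdf - adf) / (1 + exp(-u)).
// hyper: mu_a, sd_a, mu_b, sd_b, mu_g, sd_g, adf, bdf.
static double robit_logpost(const NumericVector& par,
                            const NumericVector& y, const NumericVector& n,
                            const NumericVector& dA, const NumericVector& dB,
                            const NumericVector& hyper) {
  const double alpha = par[0], b1 = par[1], b2 = par[2];
  const double g1 = par[3], g2 = par[4];
  const double lv = par[5], u = par[6];
  const double v = std::exp(lv);
  if (!R_finite(v) || v <= 0.0) return R_NegInf;
  const double adf = hyper[6], bdf = hyper[7];
  const double s = 1.0 / (1.0 + std::exp(-u));
  const double df = adf + (bdf - adf) * s;

  double lp = 0.0;
  // binomial likelihood over the local cells (empty cells contribute 0)
  for (int i = 0; i < y.size(); ++i) {
    if (n[i] <= 0.0) continue;
    const double eta = alpha + b1 * dA[i] + b2 * dB[i] +
      g1 * dA[i] * dA[i] + g2 * dB[i] * dB[i];
    const double q = R::pt(eta, v, 1, 0);
    if (q <= 0.0 || q >= 1.0) {
      // saturated link: only admissible if the data agree exactly
      if ((q <= 0.0 && y[i] > 0.0) || (q >= 1.0 && y[i] < n[i]))
        return R_NegInf;
      continue;
    }
    lp += y[i] * std::log(q) + (n[i] - y[i]) * std::log1p(-q);
  }
  // priors
  lp += R::dnorm(alpha, hyper[0], hyper[1], 1);
  lp += R::dnorm(b1, hyper[2], hyper[3], 1);
  lp += R::dnorm(b2, hyper[2], hyper[3], 1);
  lp += R::dnorm(g1, hyper[4], hyper[5], 1);
  lp += R::dnorm(g2, hyper[4], hyper[5], 1);
  // half-t(0, 1, df) prior on v > 0, with Jacobian of v = exp(lv)
  lp += M_LN2 + R::dt(v, df, 1) + lv;
  // df ~ Uniform(adf, bdf); Jacobian of the logistic transform
  lp += std::log((bdf - adf) * s * (1.0 - s));
  return lp;
}

// Adaptive random-walk Metropolis sampler for the robit model.
// Returns kept draws (after burn-in) on the original scale:
// columns alpha, b1, b2, g1, g2, v, df; plus the acceptance rate.
// [[Rcpp::export]]
List robit_mcmc_cpp(NumericVector y, NumericVector n,
                    NumericVector dA, NumericVector dB,
                    NumericVector hyper, int iters, int burnin,
                    double init_scale) {
  RNGScope scope;
  const int p = 7;
  NumericVector cur(p);
  cur[5] = 0.0;  // v = 1
  cur[6] = 0.0;  // df at the middle of its range
  double lp_cur = robit_logpost(cur, y, n, dA, dB, hyper);
  double scale = init_scale;
  // per-coordinate base scales: coefficients move more than shape params
  double base[7] = {1.0, 1.0, 1.0, 1.0, 1.0, 0.5, 1.0};

  const int keep = iters - burnin;
  NumericMatrix draws(keep, p);
  int accept = 0, win_acc = 0, win_n = 0;
  NumericVector prop(p);

  for (int it = 0; it < iters; ++it) {
    for (int j = 0; j < p; ++j)
      prop[j] = cur[j] + scale * base[j] * R::norm_rand();
    const double lp_prop = robit_logpost(prop, y, n, dA, dB, hyper);
    if (lp_prop > R_NegInf &&
        std::log(R::unif_rand()) < lp_prop - lp_cur) {
      for (int j = 0; j < p; ++j) cur[j] = prop[j];
      lp_cur = lp_prop;
      ++accept; ++win_acc;
    }
    ++win_n;
    // adapt the global proposal scale during burn-in toward ~0.3 acceptance
    if (it < burnin && win_n == 50) {
      const double rate = (double) win_acc / win_n;
      if (rate < 0.2) scale *= 0.8;
      else if (rate > 0.4) scale *= 1.25;
      win_acc = 0; win_n = 0;
    }
    if (it >= burnin) {
      const int r = it - burnin;
      for (int j = 0; j < 5; ++j) draws(r, j) = cur[j];
      draws(r, 5) = std::exp(cur[5]);
      const double s = 1.0 / (1.0 + std::exp(-cur[6]));
      draws(r, 6) = hyper[6] + (hyper[7] - hyper[6]) * s;
    }
  }
  return List::create(_["draws"] = draws,
                      _["accept_rate"] = (double) accept / iters,
                      _["scale"] = scale);
}
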