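#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the AR(1) Poisson hazard model:
//   O_T ~ Poisson(Y_T * exp(delta_T))
//   delta_1 ~ N(0, prior_var), delta_T ~ N(delta_{T-1}, prior_var)
// Component-wise random-walk proposals, adapted toward 0.44 acceptance
// during warmup (Robbins-Monro on log proposal sd), fixed afterwards.
// Uses R's RNG so reproducibility is governed by set.seed() in R.

static inline double comp_logpost(int t, double v, const NumericVector& delta,
                                  const NumericVector& O, const NumericVector& Y,
                                  double prior_var) {
  int T = delta.size();
  double lp = O[t] * v - Y[t] * std::exp(v);
  double prev = (t == 0) ? 0.0 : delta[t - 1];
  lp += -0.5 * (v - prev) * (v - prev) / prior_var;
  if (t + 1 < T) {
    double d = delta[t + 1] - v;
    lp += -0.5 * d * d / prior_var;
  }
  return lp;
}

NumericMatrix ar1_poisson_chain(NumericVector O, NumericVector Y,
                                int n_draws, int n_warmup,
                                double prior_var) {
  int T = O.size();
  NumericVector delta(T);
  for (int t = 0; t < T; ++t) {
    double rate = (O[t] + 0.5) / Y[t];       // crude init at smoothed MLE
    delta[t] = std::log(rate);
  }
  NumericVector lsd(T, std::log(0.5));       // log proposal sd
  NumericMatrix out(n_draws, T);
  int total = n_warmup + n_draws;
  for (int it = 0; it < total; ++it) {
    for (int t = 0; t < T; ++t) {
      double cur = delta[t];
      double prop = cur + std::exp(lsd[t]) * R::norm_rand();
      double lr = comp_logpost(t, prop, delta, O, Y, prior_var) -
                  comp_logpost(t, cur, delta, O, Y, prior_var);
      bool accept = std::log(R::unif_rand()) < lr;
      if (accept) delta[t] = prop;
      if (it < n_warmup) {
        double gamma = 1.0 / std::sqrt((double)(it + 1));
        lsd[t] += gamma * ((accept ? 1.0 : 0.0) - 0.44);
      }
    }
    if (it >= n_warmup)
      for (int t = 0; t < T; ++t) out(it - n_warmup, t) = delta[t];
  }
  return out;
}

extern "C" SEXP _synsurv_ar1_poisson_chain(SEXP OS, SEXP YS, SEXP n_drawsS,
                                           SEXP n_warmupS, SEXP prior_varS) {
  BEGIN_RCPP
  Rcpp::RObject res;
  Rcpp::RNGScope rngScope;
  res = Rcpp::wrap(ar1_poisson_chain(as<NumericVector>(OS),
                                     as<NumericVector>(YS),
                                     as<int>(n_drawsS), as<int>(n_warmupS),
                                     as<double>(prior_varS)));
  return res;
  END_RCPP
}
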