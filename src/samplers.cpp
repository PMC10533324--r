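#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double log1p_exp(double x) {
  if (x > 0.0) return x + std::log1p(std::exp(-x));
  return std::log1p(std::exp(x));
}

// Gibbs sampler for a K-component Gaussian mixture on (already log-scale)
// values. Priors: mu_k ~ N(0, prior_mu_sd^2), sigma_k ~ HalfNormal(prior_sigma_sd),
// weights ~ Dirichlet(alpha). sigma_k is updated by random-walk Metropolis on
// log(sigma); everything else is conjugate. After every sweep the components
// are permuted into ascending-mean order, so every retained draw satisfies
// the identifiability constraint (mu_1 <= ... <= mu_K). Latent assignments
// are resampled at the top of each sweep, so the permutation needs no z remap.
// Uses R's RNG: draws are reproducible under set.seed().
// [[Rcpp::export]]
List mixture_gibbs_cpp(NumericVector y, int K, int n_iter, int burn_in, int thin,
                       double prior_mu_sd, double prior_sigma_sd,
                       double dirichlet_alpha, double prop_sd_log_sigma) {
  const int n = y.size();
  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix mu_draws(n_keep, K), sigma_draws(n_keep, K), w_draws(n_keep, K);

  // deterministic initialisation from order statistics
  NumericVector ys = clone(y).sort();
  std::vector<double> mu(K), sigma(K), w(K);
  double y_mean = mean(y), y_sd = sd(y);
  if (n < 2 || y_sd <= 0.0) y_sd = 1.0;
  for (int k = 0; k < K; ++k) {
    int idx = (int)std::floor((k + 1.0) / (K + 1.0) * (n - 1));
    mu[k] = (K == 1) ? y_mean : ys[idx];
    sigma[k] = y_sd;
    w[k] = 1.0 / K;
  }

  std::vector<int> z(n, 0);
  std::vector<int> nk(K);
  std::vector<double> sk(K), pk(K);
  const double prior_mu_prec = 1.0 / (prior_mu_sd * prior_mu_sd);
  const double prior_sig_var = prior_sigma_sd * prior_sigma_sd;

  int keep = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // latent assignments
    std::fill(nk.begin(), nk.end(), 0);
    std::fill(sk.begin(), sk.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double d = (y[i] - mu[k]) / sigma[k];
        pk[k] = std::log(w[k]) - std::log(sigma[k]) - 0.5 * d * d;
        if (pk[k] > mx) mx = pk[k];
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { pk[k] = std::exp(pk[k] - mx); tot += pk[k]; }
      double u = R::runif(0.0, 1.0) * tot, cum = 0.0;
      int zi = K - 1;
      for (int k = 0; k < K; ++k) { cum += pk[k]; if (u <= cum) { zi = k; break; } }
      z[i] = zi;
      nk[zi] += 1;
      sk[zi] += y[i];
    }
    // weights | z
    double gtot = 0.0;
    for (int k = 0; k < K; ++k) { w[k] = R::rgamma(dirichlet_alpha + nk[k], 1.0); gtot += w[k]; }
    for (int k = 0; k < K; ++k) w[k] /= gtot;

    // means | z, sigma (conjugate normal)
    for (int k = 0; k < K; ++k) {
      double prec = nk[k] / (sigma[k] * sigma[k]) + prior_mu_prec;
      double m = (sk[k] / (sigma[k] * sigma[k])) / prec;
      mu[k] = R::rnorm(m, std::sqrt(1.0 / prec));
    }

    // sigma | z, mu: Metropolis on log sigma, Half-Normal prior
    for (int k = 0; k < K; ++k) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i)
        if (z[i] == k) { double d = y[i] - mu[k]; ss += d * d; }
      double ls_cur = std::log(sigma[k]);
      double ls_prop = ls_cur + R::rnorm(0.0, prop_sd_log_sigma);
      double s_prop = std::exp(ls_prop);
      // log target in log-sigma parameterisation (Jacobian = sigma)
      double lp_cur = -nk[k] * ls_cur - ss / (2.0 * sigma[k] * sigma[k])
                      - sigma[k] * sigma[k] / (2.0 * prior_sig_var) + ls_cur;
      double lp_prop = -nk[k] * ls_prop - ss / (2.0 * s_prop * s_prop)
                       - s_prop * s_prop / (2.0 * prior_sig_var) + ls_prop;
      if (std::log(R::runif(0.0, 1.0)) < lp_prop - lp_cur) sigma[k] = s_prop;
    }

    // restore ascending-mean order (simple insertion sort; K <= 3 in practice)
    for (int a = 1; a < K; ++a)
      for (int b = a; b > 0 && mu[b] < mu[b - 1]; --b) {
        std::swap(mu[b], mu[b - 1]);
        std::swap(sigma[b], sigma[b - 1]);
        std::swap(w[b], w[b - 1]);
      }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      for (int k = 0; k < K; ++k) {
        mu_draws(keep, k) = mu[k];
        sigma_draws(keep, k) = sigma[k];
        w_draws(keep, k) = w[k];
      }
      ++keep;
    }
  }

  return List::create(_["mu"] = mu_draws, _["sigma"] = sigma_draws,
                      _["w"] = w_draws);
}

// Random-walk Metropolis for Bayesian logistic regression of a binary
// response on one predictor (pass the predictor centred for decent mixing).
// Priors: independent N(0, prior_sd^2) on intercept and slope. Missing
// responses contribute nothing to the likelihood and are handled by the
// caller via the posterior predictive. Returns draws on the centred scale.
// [[Rcpp::export]]
List logistic_mh_cpp(NumericVector x, IntegerVector yobs, int n_iter, int burn_in,
                     int thin, double prior_sd, double prop_sd0, double prop_sd1) {
  const int n = x.size();
  const int n_keep = (n_iter - burn_in) / thin;
  NumericVector b0_draws(n_keep), b1_draws(n_keep);
  const double prior_var = prior_sd * prior_sd;

  double b0 = 0.0, b1 = 0.0;
  auto logpost = [&](double a0, double a1) {
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double eta = a0 + a1 * x[i];
      ll += yobs[i] * eta - log1p_exp(eta);
    }
    return ll - (a0 * a0 + a1 * a1) / (2.0 * prior_var);
  };
  double lp = logpost(b0, b1);

  int keep = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    double p0 = b0 + R::rnorm(0.0, prop_sd0);
    double lp_p = logpost(p0, b1);
    if (std::log(R::runif(0.0, 1.0)) < lp_p - lp) { b0 = p0; lp = lp_p; }
    double p1 = b1 + R::rnorm(0.0, prop_sd1);
    lp_p = logpost(b0, p1);
    if (std::log(R::runif(0.0, 1.0)) < lp_p - lp) { b1 = p1; lp = lp_p; }
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      b0_draws[keep] = b0;
      b1_draws[keep] = b1;
      ++keep;
    }
  }
  return List::create(_["b0"] = b0_draws, _["b1"] = b1_draws);
}
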