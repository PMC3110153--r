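#include <Rcpp.h>
using namespace Rcpp;

// Spike-and-slab Gibbs sampler for one gene.
//
// Model: y_c = mu + g1*b1*P1(x_c) + g2*b2*P2(x_c) + e_c, e ~ N(0, sigma2)
// Priors: mu flat; b_k | slab ~ N(0, tau2); g_k ~ Bern(pi);
//         sigma2 ~ IG(a_sig, b_sig); tau2 ~ IG(a_tau, b_tau) shared by the
//         gene's coefficients. The spike is an exact point mass at zero, so
//         the post-burn-in frequency of g_k = 1 is a genuine posterior
//         probability that the coefficient is nonzero.
// Each sweep updates mu, then (g_k, b_k) jointly per coefficient with b_k
// marginalized out of the g_k draw, then sigma2 and tau2.
// Uses R's RNG stream: seeding is done from R via set.seed().

static inline double rinvgamma(double shape, double scale_ig) {
  // IG(shape a, scale b): 1/X ~ Gamma(shape a, rate b)
  return 1.0 / R::rgamma(shape, 1.0 / scale_ig);
}

// [[Rcpp::export]]
List gibbs_gene(NumericVector y, NumericVector p1, NumericVector p2,
                int n_iter, int n_burnin, double pi_incl,
                double a_tau, double b_tau, double a_sig, double b_sig,
                bool fix_gamma = false, double fix_sigma2 = -1.0,
                double fix_tau2 = -1.0, double sigma2_floor = 1e-8,
                bool keep_draws = false) {
  const int n = y.size();
  if (p1.size() != n || p2.size() != n)
    stop("basis/response length mismatch");
  if (n_burnin >= n_iter) stop("burn-in must be smaller than n_iter");

  // sufficient statistics (no orthogonality assumed)
  double sum_y = 0.0, s1 = 0.0, s2 = 0.0;
  double d11 = 0.0, d22 = 0.0, d12 = 0.0, z1y = 0.0, z2y = 0.0;
  for (int i = 0; i < n; ++i) {
    sum_y += y[i];
    s1 += p1[i]; s2 += p2[i];
    d11 += p1[i] * p1[i]; d22 += p2[i] * p2[i]; d12 += p1[i] * p2[i];
    z1y += p1[i] * y[i];  z2y += p2[i] * y[i];
  }

  double mu = sum_y / n;
  double b1 = 0.0, b2 = 0.0;
  int g1 = fix_gamma ? 1 : 0, g2 = fix_gamma ? 1 : 0;
  double ybar = sum_y / n, vy = 0.0;
  for (int i = 0; i < n; ++i) vy += (y[i] - ybar) * (y[i] - ybar);
  vy = (n > 1) ? vy / (n - 1) : 1.0;
  double sigma2 = (fix_sigma2 > 0.0) ? fix_sigma2
                                     : std::max(vy, sigma2_floor);
  double tau2 = (fix_tau2 > 0.0) ? fix_tau2
                                 : (a_tau > 1.0 ? b_tau / (a_tau - 1.0) : 1.0);

  const int n_keep = n_iter - n_burnin;
  double sum_g1 = 0, sum_g2 = 0, sum_gb1 = 0, sum_gb2 = 0;
  double sum_mu = 0, sum_s2 = 0;
  NumericMatrix draws(keep_draws ? n_keep : 0, keep_draws ? 5 : 0);

  const double log_prior_odds = std::log(pi_incl) - std::log1p(-pi_incl);

  for (int it = 0; it < n_iter; ++it) {
    // mu | rest (flat prior)
    double m_mu = (sum_y - g1 * b1 * s1 - g2 * b2 * s2) / n;
    mu = R::rnorm(m_mu, std::sqrt(sigma2 / n));

    // (g1, b1) with b1 marginalized from the indicator draw
    {
      double z = z1y - mu * s1 - g2 * b2 * d12;
      double prec = d11 / sigma2 + 1.0 / tau2;
      double v = 1.0 / prec, m = v * z / sigma2;
      double log_bf = 0.5 * (std::log(v) - std::log(tau2)) + 0.5 * m * m / v;
      double logit = log_prior_odds + log_bf;
      double p = 1.0 / (1.0 + std::exp(-logit));
      g1 = fix_gamma ? 1 : (R::runif(0.0, 1.0) < p ? 1 : 0);
      b1 = g1 ? R::rnorm(m, std::sqrt(v)) : 0.0;
    }
    // (g2, b2)
    {
      double z = z2y - mu * s2 - g1 * b1 * d12;
      double prec = d22 / sigma2 + 1.0 / tau2;
      double v = 1.0 / prec, m = v * z / sigma2;
      double log_bf = 0.5 * (std::log(v) - std::log(tau2)) + 0.5 * m * m / v;
      double logit = log_prior_odds + log_bf;
      double p = 1.0 / (1.0 + std::exp(-logit));
      g2 = fix_gamma ? 1 : (R::runif(0.0, 1.0) < p ? 1 : 0);
      b2 = g2 ? R::rnorm(m, std::sqrt(v)) : 0.0;
    }

    // sigma2 | rest
    if (fix_sigma2 <= 0.0) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) {
        double r = y[i] - mu - g1 * b1 * p1[i] - g2 * b2 * p2[i];
        sse += r * r;
      }
      sigma2 = rinvgamma(a_sig + 0.5 * n, b_sig + 0.5 * sse);
      if (sigma2 < sigma2_floor) sigma2 = sigma2_floor;
    }

    // tau2 | rest: included coefficients only; prior draw when none
    if (fix_tau2 <= 0.0) {
      double q = g1 + g2;
      double ss = g1 * b1 * b1 + g2 * b2 * b2;
      tau2 = rinvgamma(a_tau + 0.5 * q, b_tau + 0.5 * ss);
    }

    if (it >= n_burnin) {
      sum_g1 += g1; sum_g2 += g2;
      sum_gb1 += g1 * b1; sum_gb2 += g2 * b2;
      sum_mu += mu; sum_s2 += sigma2;
      if (keep_draws) {
        int r = it - n_burnin;
        draws(r, 0) = mu; draws(r, 1) = g1 * b1; draws(r, 2) = g2 * b2;
        draws(r, 3) = sigma2; draws(r, 4) = tau2;
      }
    }
  }

  List out = List::create(
      _["pp1"] = sum_g1 / n_keep, _["pp2"] = sum_g2 / n_keep,
      _["beta1_mean"] = sum_gb1 / n_keep, _["beta2_mean"] = sum_gb2 / n_keep,
      _["intercept_mean"] = sum_mu / n_keep,
      _["sigma2_mean"] = sum_s2 / n_keep);
  if (keep_draws) {
    colnames(draws) = CharacterVector::create("mu", "beta1", "beta2",
                                              "sigma2", "tau2");
    out["draws"] = draws;
  }
  return out;
}
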