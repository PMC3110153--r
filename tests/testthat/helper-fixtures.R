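# shared fixtures and independent oracles

# the 13 retained start-of-estrus heat scores and the 14 mid-cycle scores
day0_scores <- function() c(0, 37, 43, 53, 137, 175, 191, 200, 206, 246,
                            248, 378, 405)
day12_scores <- function() c(2, 4, 5, 75, 157, 198, 257, 275, 318, 368,
                             383, 404, 475, 505)

# brute-force upper-tail hypergeometric: P(X >= k) by direct pmf summation
hyper_upper_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(dhyper(k:hi, K, N - K, n))
}

# closed-form conjugate posterior mean of (mu, b1, b2) with indicators
# clamped at 1 and variances fixed: (X'X + D)^-1 X'y, D = diag(0, s2/t2, s2/t2)
conjugate_mean_oracle <- function(y, basis, sigma2, tau2) {
  X <- cbind(1, basis$P[, "P1"], basis$P[, "P2"])
  D <- diag(c(0, sigma2 / tau2, sigma2 / tau2))
  solve(crossprod(X) + D, crossprod(X, y))[, 1]
}

# independent Metropolis-within-Gibbs sampler for the same spike-and-slab
# posterior (fixed variances), used to validate the collapsed Gibbs moves:
# proposes flipping one indicator at a time and accepts by the exact joint
# density ratio with beta integrated out analytically per coefficient.
metropolis_gamma_oracle <- function(y, basis, sigma2, tau2, pi_incl,
                                    n_iter = 40000, seed = 1) {
  set.seed(seed)
  X <- cbind(basis$P[, "P1"], basis$P[, "P2"])
  n <- length(y)
  # log marginal likelihood of y | gamma (mu flat, beta integrated out)
  logml <- function(g) {
    Xg <- cbind(rep(1, n), X[, g == 1, drop = FALSE])
    prior_prec <- diag(c(0, rep(sigma2 / tau2, sum(g))), nrow = 1 + sum(g))
    A <- crossprod(Xg) + prior_prec
    b <- crossprod(Xg, y)
    quad <- (sum(y^2) - t(b) %*% solve(A, b)) / sigma2
    -0.5 * quad - 0.5 * determinant(A)$modulus +
      0.5 * sum(g == 1) * log(sigma2 / tau2) +
      sum(g) * log(pi_incl) + sum(1 - g) * log(1 - pi_incl)
  }
  g <- c(0, 0)
  counts <- matrix(0, 2, 2, dimnames = list(g1 = 0:1, g2 = 0:1))
  cur <- logml(g)
  for (it in seq_len(n_iter)) {
    j <- sample(1:2, 1)
    gp <- g; gp[j] <- 1 - gp[j]
    prop <- logml(gp)
    if (log(runif(1)) < prop - cur) { g <- gp; cur <- prop }
    counts[g[1] + 1, g[2] + 1] <- counts[g[1] + 1, g[2] + 1] + 1
  }
  counts / n_iter
}

tiny_spec <- function(...) {
  model_spec(n_iter = 2000L, n_burnin = 1000L, ...)
}

# small simulated dataset shared by selection/io tests
small_sim <- function(n_probes = 60, frac_linear = 0.1, frac_quadratic = 0.1,
                      seed = 77, ...) {
  cfg <- sim_config(n_probes = n_probes, frac_linear = frac_linear,
                    frac_quadratic = frac_quadratic, seed = seed, ...)
  ph <- simulate_phenotypes(cfg)
  c(list(config = cfg, phenotypes = ph), simulate_expression(cfg, ph))
}
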