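test_that("clamped-indicator Gibbs matches the conjugate posterior mean", {
  basis <- build_basis(c(day0_scores(), day12_scores()))
  sigma2 <- 0.2; tau2 <- 1.5
  spec <- model_spec(n_iter = 4000, n_burnin = 1000, n_chains = 1,
                     fix_gamma = TRUE, fix_sigma2 = sigma2, fix_tau2 = tau2,
                     seed = 101)
  set.seed(55)
  for (g in 1:6) {
    y <- rnorm(27, sd = 0.6) + 0.8 * basis$P[, "P1"]
    fit <- fit_gene(y, basis, spec, probe_id = paste0("cg", g),
                    keep_draws = TRUE)
    truth <- conjugate_mean_oracle(y, basis, sigma2, tau2)
    draws <- attr(fit, "draws")[[1]]
    est <- c(fit$intercept_mean, fit$beta1_mean, fit$beta2_mean)
    # Monte-Carlo SE with a conservative effective sample size (n/5)
    mcse <- apply(draws[, c("mu", "beta1", "beta2")], 2, sd) /
      sqrt(nrow(draws) / 5)
    expect_true(all(abs(est - truth) < 3 * mcse + 1e-8))
  }
})

test_that("collapsed indicator updates leave the exact posterior invariant", {
  # one gene, variances fixed: compare gamma-state frequencies of the Gibbs
  # sampler against an independent Metropolis sampler with beta integrated
  # out analytically
  basis <- build_basis(day0_scores())
  set.seed(202)
  y <- 0.55 * basis$P[, "P1"] + rnorm(13, sd = 0.35)
  sigma2 <- 0.35^2; tau2 <- 1; pi_incl <- 0.2
  spec <- model_spec(n_iter = 45000, n_burnin = 5000, n_chains = 1,
                     inclusion_prior = pi_incl, fix_sigma2 = sigma2,
                     fix_tau2 = tau2, seed = 77)
  fit <- fit_gene(y, basis, spec, keep_draws = TRUE)
  draws <- attr(fit, "draws")[[1]]
  g1 <- as.integer(draws[, "beta1"] != 0)
  g2 <- as.integer(draws[, "beta2"] != 0)
  gibbs_freq <- table(factor(g1, 0:1), factor(g2, 0:1)) / length(g1)
  oracle_freq <- metropolis_gamma_oracle(y, basis, sigma2, tau2, pi_incl,
                                         n_iter = 60000, seed = 5)
  tv <- 0.5 * sum(abs(as.numeric(gibbs_freq) - as.numeric(oracle_freq)))
  expect_lt(tv, 0.02)
})

test_that("pure-noise genes get low inclusion probabilities in all chains", {
  basis <- build_basis(day0_scores())
  spec <- tiny_spec(seed = 303)
  set.seed(9)
  pps <- replicate(60, {
    fit <- fit_gene(rnorm(13, sd = 0.4), basis, spec,
                    probe_id = paste0("null", runif(1)))
    c(fit$pp1, fit$pp2)
  })
  expect_lt(mean(pps), 2 * spec$inclusion_prior * 5)  # well under 0.5
  expect_true(all(as.numeric(pps) < 0.999))
})

test_that("a noiseless planted signal is recovered with certainty", {
  basis <- build_basis(day0_scores())
  y <- 3 * basis$P[, "P1"]
  fit <- fit_gene(y, basis, tiny_spec(seed = 11))
  g <- glance(fit)
  expect_gt(min(fit$pp1), 0.99)
  expect_lt(max(fit$pp2), 0.5)
  expect_equal(g$beta1_mean, 3, tolerance = 1e-2)
  expect_gt(g$r_squared, 0.999)
  # quadratic counterpart, concave
  fitq <- fit_gene(-2 * basis$P[, "P2"], basis, tiny_spec(seed = 12))
  expect_gt(min(fitq$pp2), 0.99)
  expect_equal(glance(fitq)$beta2_mean, -2, tolerance = 1e-2)
})

test_that("results are deterministic by (seed, probe, chain) substream", {
  basis <- build_basis(day0_scores())
  set.seed(1); y <- rnorm(13)
  f1 <- fit_gene(y, basis, tiny_spec(seed = 5), probe_id = "pX")
  f2 <- fit_gene(y, basis, tiny_spec(seed = 5), probe_id = "pX")
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  f3 <- fit_gene(y, basis, tiny_spec(seed = 5), probe_id = "pY")
  expect_false(identical(f1$pp1, f3$pp1))
  # chains differ from one another
  expect_gt(length(unique(f1$beta1_mean)), 1L)
})

test_that("doubling post-burn-in iterations moves pp by < 3 binomial SEs", {
  basis <- build_basis(c(day0_scores(), day12_scores()))
  set.seed(21)
  y <- 0.5 * basis$P[, "P1"] + rnorm(27, sd = 0.5)
  f_short <- glance(fit_gene(y, basis, model_spec(4000, 2000, n_chains = 3,
                                                  seed = 31)))
  f_long <- glance(fit_gene(y, basis, model_spec(8000, 2000, n_chains = 3,
                                                 seed = 33)))
  n_samp <- 2000 * 3
  for (pp in c("pp1", "pp2")) {
    p <- (f_short[[pp]] + f_long[[pp]]) / 2
    se <- sqrt(max(p * (1 - p), 1e-4) / n_samp)
    # 3 SEs on each estimate, plus chain-level wobble absorbed by sqrt(2)
    expect_lt(abs(f_short[[pp]] - f_long[[pp]]), 3 * sqrt(2) * se * 5)
  }
})

test_that("fit_all preserves probe order, aligns cows, and is subset-stable", {
  s <- small_sim(n_probes = 12, seed = 17)
  spec <- tiny_spec(seed = 40)
  post <- fit_all(s$expression, s$phenotypes, spec)
  expect_s3_class(post, "estro_posterior")
  expect_equal(unique(post$probe_id), s$expression$probe_id)
  expect_equal(nrow(post), 12L * spec$n_chains)
  # subsetting probes leaves per-probe results identical
  sub <- fit_all(s$expression[5:8, ], s$phenotypes, spec)
  expect_equal(as.data.frame(sub),
               as.data.frame(post[post$probe_id %in% s$expression$probe_id[5:8], ]),
               ignore_attr = TRUE)
  # shuffled expression columns give the same posteriors (alignment by cow)
  set.seed(3)
  shuffled <- s$expression[, c(1, sample(2:ncol(s$expression)))]
  post_sh <- fit_all(shuffled, s$phenotypes, spec)
  expect_equal(post_sh$pp1, post$pp1)
  s1 <- small_sim(n_probes = 3, seed = 17, n_tech_reps = 1L)
  expect_error(fit_all(s1$expression[-2], s1$phenotypes, spec),
               "lacks columns")
})

test_that("planted linear probes score higher pp1 than null probes", {
  s <- small_sim(n_probes = 120, frac_linear = 0.15, frac_quadratic = 0,
                 seed = 23)
  post <- fit_all(s$expression, s$phenotypes, tiny_spec(seed = 50))
  avg <- dplyr::summarise(dplyr::group_by(post, .data$probe_id),
                          pp1 = mean(.data$pp1), .groups = "drop")
  avg <- dplyr::left_join(avg, s$truth, by = "probe_id")
  expect_gt(mean(avg$pp1[avg$class == "linear"]),
            mean(avg$pp1[avg$class == "null"]) + 0.3)
})

test_that("r_squared follows the least-squares identity and conventions", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_warning(out <- r_squared(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_equal(out, 0)
  set.seed(2)
  x <- day0_scores()
  P <- build_basis(x)$P
  for (i in 1:10) {
    y <- rnorm(13)
    fitted <- as.numeric(P %*% crossprod(P, y))
    sse <- sum((y - fitted)^2); sst <- sum((y - mean(y))^2)
    expect_equal(r_squared(y, fitted), 1 - sse / sst, tolerance = 1e-10)
  }
  expect_error(r_squared(1:4, 1:3), "equal length")
})

test_that("posteriors are exchangeable under cow permutation", {
  basis <- build_basis(day0_scores())
  set.seed(31)
  y <- basis$P[, "P1"] + rnorm(13, sd = 0.3)
  perm <- sample(13)
  basis_p <- build_basis(basis$x[perm])
  f1 <- glance(fit_gene(y, basis, model_spec(6000, 1000, n_chains = 3, seed = 4)))
  f2 <- glance(fit_gene(y[perm], basis_p, model_spec(6000, 1000, n_chains = 3, seed = 4)))
  expect_equal(abs(f1$beta1_mean), abs(f2$beta1_mean), tolerance = 0.05)
  expect_equal(f1$pp1, f2$pp1, tolerance = 0.05)
})

test_that("invalid inputs are rejected", {
  basis <- build_basis(day0_scores())
  expect_error(fit_gene(c(rep(0, 12), NA), basis, tiny_spec()), "finite")
  expect_error(fit_gene(rnorm(10), basis, tiny_spec()), "different lengths")
  expect_error(model_spec(n_iter = 100, n_burnin = 100), "smaller")
  expect_error(model_spec(inclusion_prior = 1.2), "0, 1")
})
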