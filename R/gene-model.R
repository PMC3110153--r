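#' Model and sampler settings
#'
#' Settings of the per-gene Bayesian variable-selection model. The model for
#' one gene's M-values is
#' \deqn{y_c = \mu + \gamma_1\beta_1 P_1(x_c) + \gamma_2\beta_2 P_2(x_c) + e_c,}
#' with \eqn{e_c \sim N(0, \sigma^2)}, a flat prior on \eqn{\mu}, a
#' point-mass-at-zero spike and Gaussian slab \eqn{N(0, \tau^2)} on each
#' coefficient, Bernoulli(\eqn{\pi}) inclusion indicators, and inverse-gamma
#' priors on \eqn{\sigma^2} and the gene-shared slab variance \eqn{\tau^2}.
#' The posterior inclusion probability of a coefficient is the post-burn-in
#' frequency of its indicator.
#'
#' @param n_iter Gibbs iterations per chain (default 10000).
#' @param n_burnin burn-in iterations discarded (default 5000).
#' @param n_chains independent chains with distinct RNG substreams
#'   (default 5).
#' @param inclusion_prior prior inclusion probability \eqn{\pi} (default
#'   0.05, chosen so an all-null panel selects well under 1\% of probes at
#'   the 0.80 consensus rule).
#' @param slab_prior `c(shape, scale)` of the inverse-gamma prior on the
#'   slab variance \eqn{\tau^2} (default `c(2, 1)`, prior mean 1).
#' @param noise_prior `c(shape, scale)` of the inverse-gamma prior on
#'   \eqn{\sigma^2} (default `c(0.01, 0.01)`, vague, so the residual sum of
#'   squares dominates the variance posterior even at small n).
#' @param seed master seed; the stream for each (probe, chain) is derived
#'   from it so results do not depend on probe subsetting or ordering.
#' @param fix_gamma clamp both indicators to 1 (validation use).
#' @param fix_sigma2,fix_tau2 fix a variance at the given positive value
#'   instead of sampling it (validation use); `NULL` to sample.
#' @param sigma2_floor lower bound on sampled \eqn{\sigma^2} so that
#'   noise-free fixtures remain numerically stable.
#' @return a `model_spec` list.
#' @export
model_spec <- function(n_iter = 10000L, n_burnin = 5000L, n_chains = 5L,
                       inclusion_prior = 0.05,
                       slab_prior = c(2, 1), noise_prior = c(0.01, 0.01),
                       seed = 1L, fix_gamma = FALSE,
                       fix_sigma2 = NULL, fix_tau2 = NULL,
                       sigma2_floor = 1e-8) {
  n_iter <- assert_count(n_iter, "n_iter", min = 2L)
  n_burnin <- assert_count(n_burnin, "n_burnin", min = 0L)
  if (n_burnin >= n_iter) abort("`n_burnin` must be smaller than `n_iter`.")
  if (inclusion_prior <= 0 || inclusion_prior >= 1) {
    abort("`inclusion_prior` must lie in (0, 1).")
  }
  stopifnot(length(slab_prior) == 2L, all(slab_prior > 0),
            length(noise_prior) == 2L, all(noise_prior > 0))
  structure(list(
    n_iter = n_iter, n_burnin = n_burnin,
    n_chains = assert_count(n_chains, "n_chains"),
    inclusion_prior = inclusion_prior,
    slab_prior = as.numeric(slab_prior),
    noise_prior = as.numeric(noise_prior),
    seed = assert_count(seed, "seed", min = 0L),
    fix_gamma = isTRUE(fix_gamma),
    fix_sigma2 = fix_sigma2 %||% -1, fix_tau2 = fix_tau2 %||% -1,
    sigma2_floor = sigma2_floor
  ), class = "model_spec")
}

run_chains <- function(y, basis, spec, probe_id, keep_draws = FALSE) {
  p1 <- basis$P[, "P1"]
  p2 <- basis$P[, "P2"]
  draws <- vector("list", spec$n_chains)
  rows <- purrr::map(seq_len(spec$n_chains), function(ch) {
    res <- withr::with_seed(
      derive_seed(spec$seed, probe_id, index = ch),
      gibbs_gene(y, p1, p2,
                 n_iter = spec$n_iter, n_burnin = spec$n_burnin,
                 pi_incl = spec$inclusion_prior,
                 a_tau = spec$slab_prior[1], b_tau = spec$slab_prior[2],
                 a_sig = spec$noise_prior[1], b_sig = spec$noise_prior[2],
                 fix_gamma = spec$fix_gamma,
                 fix_sigma2 = spec$fix_sigma2, fix_tau2 = spec$fix_tau2,
                 sigma2_floor = spec$sigma2_floor,
                 keep_draws = keep_draws)
    )
    if (keep_draws) draws[[ch]] <<- res$draws
    fitted <- res$intercept_mean + res$beta1_mean * p1 + res$beta2_mean * p2
    tibble(probe_id = probe_id, chain = ch,
           pp1 = res$pp1, pp2 = res$pp2,
           beta1_mean = res$beta1_mean, beta2_mean = res$beta2_mean,
           intercept_mean = res$intercept_mean,
           sigma2_mean = res$sigma2_mean,
           r_squared = r_squared(y, fitted, quiet = TRUE))
  })
  list(table = bind_rows(rows), draws = draws)
}

#' Fit the selection model to one gene
#'
#' Runs `n_chains` independent Gibbs chains on one gene's M-values and
#' returns, per chain, the posterior inclusion probabilities `pp1`
#' (linear) and `pp2` (quadratic), posterior means of the selected
#' coefficients (averages of \eqn{\gamma_k\beta_k}, so shrunk through the
#' spike), the intercept and noise-variance means, and the squared
#' correlation of the posterior-mean fit with the data.
#'
#' @param y numeric vector of one probe's M-values, one per cow, aligned
#'   with `basis$x`.
#' @param basis an [build_basis()] result over the same cows.
#' @param spec a [model_spec()].
#' @param probe_id identifier used to derive the RNG substream (default
#'   `"gene"`).
#' @param keep_draws keep the post-burn-in draws (list of one matrix per
#'   chain, columns `mu`, `beta1`, `beta2`, `sigma2`, `tau2`) in the
#'   `draws` attribute.
#' @return a tibble of class `estro_fit`, one row per chain, with
#'   attributes `y` and `basis`.
#' @export
#' @examples
#' b <- build_basis(seq(0, 500, length.out = 13))
#' fit <- fit_gene(3 * b$P[, "P1"], b, model_spec(n_iter = 2000,
#'                                                n_burnin = 1000))
#' glance(fit)
fit_gene <- function(y, basis, spec = model_spec(), probe_id = "gene",
                     keep_draws = FALSE) {
  stopifnot(inherits(basis, "ortho_basis"), inherits(spec, "model_spec"))
  if (!is.numeric(y) || anyNA(y) || any(!is.finite(y))) {
    abort("`y` must be finite numeric M-values.")
  }
  if (length(y) != length(basis$x)) {
    abort("`y` and the basis covariate have different lengths.")
  }
  if (length(y) < 4L) abort("too few observations for the degree-2 model.")
  res <- run_chains(y, basis, spec, probe_id, keep_draws = keep_draws)
  out <- res$table
  class(out) <- c("estro_fit", class(out))
  attr(out, "y") <- y
  attr(out, "basis") <- basis
  if (keep_draws) attr(out, "draws") <- res$draws
  out
}

#' Fit the selection model to every probe
#'
#' Applies [fit_gene()] independently to each row of an expression matrix.
#' Columns are aligned to the basis covariate by cow identifier; technical
#' replicate columns (`cow:rep`) are averaged per cow first.
#'
#' @param expression tibble: `probe_id` plus one numeric column per cow (or
#'   per cow:replicate).
#' @param phenotypes phenotype tibble with `cow_id` and `avg_heat_score`
#'   for the cows to analyse (excluded rows, if flagged, are dropped).
#' @param spec a [model_spec()].
#' @param basis optional pre-built basis; defaults to the degree-2 basis of
#'   the retained cows' heat scores.
#' @param progress_every log a progress line every this many probes
#'   (0 = silent).
#' @return a tibble of class `estro_posterior`: one row per probe x chain
#'   with the columns of [fit_gene()], probe order preserved.
#' @export
fit_all <- function(expression, phenotypes, spec = model_spec(),
                    basis = NULL, progress_every = 0L) {
  check_expression_matrix(expression)
  check_phenotype_table(phenotypes)
  if ("excluded" %in% names(phenotypes)) {
    phenotypes <- filter(phenotypes, !.data$excluded)
  }
  expression <- collapse_replicates(expression)
  missing_cows <- setdiff(phenotypes$cow_id, names(expression))
  if (length(missing_cows)) {
    abort(paste0("expression matrix lacks columns for cows: ",
                 paste(missing_cows, collapse = ", ")))
  }
  basis <- basis %||% build_basis(phenotypes$avg_heat_score, degree = 2L)
  M <- as.matrix(expression[phenotypes$cow_id])
  out <- purrr::map(seq_len(nrow(M)), function(g) {
    if (progress_every > 0L && g %% progress_every == 0L) {
      message(sprintf("fit_all: %d / %d probes", g, nrow(M)))
    }
    run_chains(M[g, ], basis, spec, expression$probe_id[g])$table
  }) |> bind_rows()
  class(out) <- c("estro_posterior", class(out))
  attr(out, "n_chains") <- spec$n_chains
  out
}

#' Fit quality as squared correlation
#'
#' The R-squared of a per-gene fit: the squared Pearson correlation between
#' the observed M-values and the posterior-mean fitted values. Returns 0
#' (with a warning) when either vector has zero variance.
#'
#' @param y observed values.
#' @param fitted fitted values, same length, length >= 3.
#' @param quiet suppress the zero-variance warning.
#' @return a number in `[0, 1]`.
#' @export
r_squared <- function(y, fitted, quiet = FALSE) {
  if (length(y) != length(fitted) || length(y) < 3L) {
    abort("`y` and `fitted` must have equal length >= 3.")
  }
  if (sd(y) == 0 || sd(fitted) == 0) {
    if (!quiet) warn("zero variance in `y` or `fitted`; R-squared set to 0.")
    return(0)
  }
  cor(y, fitted)^2
}

#' Empirical-Bayes noise-variance hyperprior
#'
#' Estimates the inverse-gamma hyperprior of the per-gene residual variances
#' by pooling information across genes: ordinary least-squares residual
#' variances on the basis are fit to a scaled F distribution
#' (`limma::fitFDist`), whose `(df0, s0^2)` translate to inverse-gamma
#' `shape = df0 / 2`, `scale = df0 * s0^2 / 2`.
#'
#' @inheritParams fit_all
#' @return `c(shape, scale)` usable as `noise_prior` in [model_spec()].
#' @export
estimate_noise_prior <- function(expression, phenotypes, basis = NULL) {
  if (!requireNamespace("limma", quietly = TRUE)) {
    abort("estimate_noise_prior() needs the limma package.")
  }
  check_expression_matrix(expression)
  if ("excluded" %in% names(phenotypes)) {
    phenotypes <- filter(phenotypes, !.data$excluded)
  }
  expression <- collapse_replicates(expression)
  basis <- basis %||% build_basis(phenotypes$avg_heat_score, degree = 2L)
  M <- as.matrix(expression[phenotypes$cow_id])
  H <- basis$P # orthonormal, includes the constant column
  resid <- M - M %*% H %*% t(H)
  df <- ncol(M) - ncol(H)
  s2 <- rowSums(resid^2) / df
  fd <- limma::fitFDist(s2, df1 = df)
  if (!is.finite(fd$df2)) {
    warn("no evidence of variance heterogeneity; returning a weak prior.")
    return(c(2, fd$scale))
  }
  c(shape = fd$df2 / 2, scale = fd$df2 * fd$scale / 2)
}
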