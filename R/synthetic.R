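#' Simulation configuration
#'
#' Parameters of the synthetic study: two groups of cows (start of estrus
#' and mid cycle), a probe panel in which a minority of probes carry a
#' planted linear or quadratic dependence of M-value on heat score,
#' gene-specific residual variances drawn from an inverse-gamma, and per-cow
#' dye-swap technical replicates.
#'
#' Defaults mirror the study design this generator emulates: 13 + 14 cows,
#' heat-score distributions with group means/SDs 178.4/125.7 and 244.7/175.4
#' (left-truncated at zero, since scores are non-negative), two technical
#' replicates per cow, and per-gene residual variances averaging ~0.13
#' (residual SD 0.3-0.4, typical of normalized two-color array M-values).
#'
#' @param n_cows_day0,n_cows_day12 cows per group.
#' @param n_probes number of probes on the simulated array.
#' @param frac_linear,frac_quadratic proportions of probes with a planted
#'   linear / quadratic association; the remainder are null.
#' @param effect_scale effect-size scale: planted `|beta|` are drawn uniform
#'   on `[0.5, 1.5] * effect_scale` (units of M-value per unit of the
#'   orthonormal covariate), with random sign.
#' @param noise_shape,noise_scale shape/scale of the inverse-gamma
#'   distribution of per-gene residual variances `sigma2`.
#' @param mean_day0,sd_day0,mean_day12,sd_day12 target mean and SD of each
#'   group's heat scores. Scores are drawn from a normal left-truncated at
#'   zero whose pre-truncation parameters are solved so the truncated
#'   distribution has exactly these moments.
#' @param n_tech_reps dye-swap technical replicates per cow (independent
#'   noise around the same per-cow signal).
#' @param seed master seed; per-stage substreams are derived from it so the
#'   phenotype and expression draws are independently reproducible.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cows_day0 = 13L, n_cows_day12 = 14L,
                       n_probes = 1000L,
                       frac_linear = 0.05, frac_quadratic = 0.05,
                       effect_scale = 2,
                       noise_shape = 4, noise_scale = 0.4,
                       mean_day0 = 178.4, sd_day0 = 125.7,
                       mean_day12 = 244.7, sd_day12 = 175.4,
                       n_tech_reps = 2L, seed = 1L) {
  cfg <- list(
    n_cows_day0 = assert_count(n_cows_day0, "n_cows_day0"),
    n_cows_day12 = assert_count(n_cows_day12, "n_cows_day12"),
    n_probes = assert_count(n_probes, "n_probes"),
    frac_linear = assert_scalar_number(frac_linear, "frac_linear", min = 0),
    frac_quadratic = assert_scalar_number(frac_quadratic, "frac_quadratic", min = 0),
    effect_scale = assert_scalar_number(effect_scale, "effect_scale", min = 0),
    noise_shape = assert_scalar_number(noise_shape, "noise_shape", min = 0, allow_zero = FALSE),
    noise_scale = assert_scalar_number(noise_scale, "noise_scale", min = 0),
    mean_day0 = mean_day0, sd_day0 = sd_day0,
    mean_day12 = mean_day12, sd_day12 = sd_day12,
    n_tech_reps = assert_count(n_tech_reps, "n_tech_reps"),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$frac_linear + cfg$frac_quadratic > 1) {
    abort("frac_linear + frac_quadratic must be <= 1.")
  }
  if (cfg$sd_day0 < 0 || cfg$sd_day12 < 0) {
    abort("heat-score SDs must be non-negative.")
  }
  structure(cfg, class = "sim_config")
}

# N(mu, s) left-truncated at zero via inverse-CDF, exact under seed
rtruncnorm0 <- function(n, mu, s) {
  if (s == 0) return(rep(mu, n))
  lo <- pnorm(0, mu, s)
  qnorm(runif(n, lo, 1), mu, s)
}

# pre-truncation (mu, s) such that N(mu, s) truncated at zero has the target
# mean and SD: the configured group moments describe the observed scores,
# which are themselves nonnegative
trunc0_params <- function(target_mean, target_sd) {
  if (target_sd == 0) return(c(mu = target_mean, s = 0))
  moments <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    a <- -mu / s
    lam <- dnorm(a) / (1 - pnorm(a))
    m <- mu + s * lam
    v <- s^2 * (1 + a * lam - lam^2)
    c(m, sqrt(max(v, 0)))
  }
  obj <- function(par) sum((moments(par) - c(target_mean, target_sd))^2)
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], s = exp(fit$par[2]))
}

#' Simulate per-cow average heat scores
#'
#' Draws one average heat score per cow from a group-specific normal
#' left-truncated at zero (scores are non-negative by construction).
#'
#' @param config a [sim_config()].
#' @return phenotype tibble: `cow_id`, `group`, `avg_heat_score`.
#' @export
#' @examples
#' simulate_phenotypes(sim_config(seed = 7))
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p0 <- trunc0_params(config$mean_day0, config$sd_day0)
  p12 <- trunc0_params(config$mean_day12, config$sd_day12)
  withr::with_seed(derive_seed(config$seed, "phenotypes"), {
    tibble(
      cow_id = c(sprintf("sim_d0_%02d", seq_len(config$n_cows_day0)),
                 sprintf("sim_d12_%02d", seq_len(config$n_cows_day12))),
      group = rep(c("day0", "day12"),
                  c(config$n_cows_day0, config$n_cows_day12)),
      avg_heat_score = c(
        rtruncnorm0(config$n_cows_day0, p0["mu"], p0["s"]),
        rtruncnorm0(config$n_cows_day12, p12["mu"], p12["s"]))
    )
  })
}

#' Simulate an M-value expression matrix with known truth
#'
#' For each probe a class (null / linear / quadratic) is drawn with the
#' configured proportions, a residual variance from the inverse-gamma, and
#' planted coefficients on the orthonormal phenotype basis. M-values are
#' `beta1 * P1(x) + beta2 * P2(x) + noise`; technical replicates are
#' independent re-draws of the noise around the same per-cow signal.
#'
#' @param config a [sim_config()].
#' @param phenotypes phenotype tibble (e.g. from [simulate_phenotypes()]);
#'   its cow count must match the config.
#' @return a list with `expression` (tibble: `probe_id` plus one numeric
#'   column per cow/replicate, named `cow:rep` when `n_tech_reps > 1`) and
#'   `truth` (tibble: `probe_id`, `class`, `beta1`, `beta2`, `sigma2`).
#' @export
simulate_expression <- function(config, phenotypes) {
  stopifnot(inherits(config, "sim_config"))
  check_phenotype_table(phenotypes)
  n_cows <- nrow(phenotypes)
  if (n_cows != config$n_cows_day0 + config$n_cows_day12) {
    abort("phenotype table size does not match the configured cow counts.")
  }
  basis <- build_basis(phenotypes$avg_heat_score, degree = 2L)
  p1 <- basis$P[, "P1"]; p2 <- basis$P[, "P2"]
  G <- config$n_probes
  withr::with_seed(derive_seed(config$seed, "expression"), {
    class <- sample(c("linear", "quadratic", "null"), G, replace = TRUE,
                    prob = c(config$frac_linear, config$frac_quadratic,
                             1 - config$frac_linear - config$frac_quadratic))
    mag <- runif(G, 0.5, 1.5) * config$effect_scale *
      sample(c(-1, 1), G, replace = TRUE)
    beta1 <- ifelse(class == "linear", mag, 0)
    beta2 <- ifelse(class == "quadratic", mag, 0)
    sigma2 <- if (config$noise_scale == 0) rep(0, G) else
      1 / rgamma(G, shape = config$noise_shape, rate = config$noise_scale)
    reps <- config$n_tech_reps
    signal <- outer(beta1, p1) + outer(beta2, p2)   # G x n_cows
    M <- matrix(0, G, n_cows * reps)
    for (r in seq_len(reps)) {
      cols <- (seq_len(n_cows) - 1L) * reps + r
      M[, cols] <- signal +
        matrix(rnorm(G * n_cows, sd = rep(sqrt(sigma2), n_cows)), G, n_cows)
    }
    probe_id <- sprintf("probe_%05d", seq_len(G))
    col_ids <- if (reps > 1L) {
      paste0(rep(phenotypes$cow_id, each = reps), ":", seq_len(reps))
    } else phenotypes$cow_id
    expr <- bind_cols(tibble(probe_id = probe_id),
                      as_tibble(setNames(as.data.frame(M), col_ids)))
    truth <- tibble(probe_id = probe_id, class = class,
                    beta1 = beta1, beta2 = beta2, sigma2 = sigma2)
    list(expression = expr, truth = truth)
  })
}

#' Average technical replicates per cow
#'
#' Collapses `cow:rep` columns of a simulated (or read) expression matrix to
#' one column per cow by averaging, the default way dye-swap replicates
#' enter the model.
#'
#' @param expression tibble with `probe_id` and `cow:rep` columns.
#' @return tibble with `probe_id` and one column per cow.
#' @export
collapse_replicates <- function(expression) {
  check_expression_matrix(expression)
  value_cols <- setdiff(names(expression), "probe_id")
  cows <- sub(":.*$", "", value_cols)
  if (!anyDuplicated(cows)) return(expression)
  M <- as.matrix(expression[value_cols])
  avg <- vapply(unique(cows),
                function(cw) rowMeans(M[, cows == cw, drop = FALSE]),
                numeric(nrow(M)))
  if (is.null(dim(avg))) {
    avg <- matrix(avg, nrow = 1, dimnames = list(NULL, unique(cows)))
  }
  bind_cols(expression["probe_id"], as_tibble(avg))
}
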