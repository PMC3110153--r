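#' Per-coefficient summary of a gene fit
#'
#' One row per chain and coefficient: the posterior inclusion probability
#' and posterior mean of the linear and quadratic terms.
#'
#' @param x an `estro_fit` from [fit_gene()].
#' @param ... unused.
#' @return tibble with `chain`, `term` (`linear`/`quadratic`), `estimate`
#'   (posterior mean of \eqn{\gamma\beta}) and `posterior_prob`.
#' @exportS3Method generics::tidy
tidy.estro_fit <- function(x, ...) {
  tbl <- as_tibble(x)
  bind_rows(
    tbl |> select("chain", estimate = "beta1_mean",
                  posterior_prob = "pp1") |> mutate(term = "linear"),
    tbl |> select("chain", estimate = "beta2_mean",
                  posterior_prob = "pp2") |> mutate(term = "quadratic")
  ) |>
    select("chain", "term", "estimate", "posterior_prob") |>
    arrange(.data$chain, .data$term)
}

#' One-row summary of a gene fit
#'
#' Chain-averaged inclusion probabilities, coefficient means, residual
#' variance and fit R-squared.
#'
#' @inheritParams tidy.estro_fit
#' @return a one-row tibble.
#' @exportS3Method generics::glance
glance.estro_fit <- function(x, ...) {
  as_tibble(x) |>
    summarise(n_chains = n(),
              across(c("pp1", "pp2", "beta1_mean", "beta2_mean",
                       "intercept_mean", "sigma2_mean", "r_squared"), mean))
}

#' Plot a gene's association with the phenotype
#'
#' Scatter of one probe's M-values against heat score with the
#' posterior-mean polynomial curve per chain overlaid — the per-gene
#' association-pattern plot.
#'
#' @param object an `estro_fit` from [fit_gene()] (fitted with its default
#'   attributes intact).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.estro_fit <- function(object, ...) {
  basis <- attr(object, "basis")
  y <- attr(object, "y")
  if (is.null(basis) || is.null(y)) {
    abort("this fit carries no data; refit with fit_gene().")
  }
  pts <- tibble(heat_score = basis$x, m_value = y)
  grid_x <- seq(min(basis$x), max(basis$x), length.out = 100)
  # interpolate the orthonormal polynomials onto the grid via the
  # polynomial coefficients recovered from the observed design
  coefs <- qr.solve(outer(basis$x, 0:basis$degree, `^`), basis$P)
  Pg <- outer(grid_x, 0:basis$degree, `^`) %*% coefs
  curves <- purrr::map(seq_len(nrow(object)), function(i) {
    tibble(chain = factor(object$chain[i]), heat_score = grid_x,
           m_value = object$intercept_mean[i] +
             object$beta1_mean[i] * Pg[, 2] + object$beta2_mean[i] * Pg[, 3])
  }) |> bind_rows()
  ggplot2::ggplot(pts, ggplot2::aes(.data$heat_score, .data$m_value)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(colour = .data$chain), alpha = 0.8) +
    ggplot2::labs(x = "average heat score", y = "M-value",
                  colour = "chain") +
    ggplot2::theme_minimal()
}

#' Phenotype summary bar plot
#'
#' Group means with SD error bars from [summarize_heat_scores()] output.
#'
#' @param object a summary tibble (`group`, `n`, `mean`, `sd`, ...).
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_phenotype_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.15) +
    ggplot2::labs(x = NULL, y = "average heat score") +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' EASE significance against fold of study-set hits for the top gene sets.
#'
#' @param object an enrichment tibble from [enrich()].
#' @param top number of sets to show (by EASE p-value).
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_enrichment <- function(object, top = 20L, ...) {
  df <- utils::head(arrange(object, .data$ease_p), top) |>
    mutate(set_id = factor(.data$set_id, levels = rev(.data$set_id)))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$ease_p), .data$set_id)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k,
                                     colour = .data$bh_fdr < 0.2)) +
    ggplot2::labs(x = expression(-log[10] ~ "EASE p"), y = NULL,
                  size = "hits", colour = "FDR < 20%") +
    ggplot2::theme_minimal()
}
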