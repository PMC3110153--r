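#' Probes significant in one chain
#'
#' A probe is significant in a chain when the posterior probability that at
#' least one regression coefficient is nonzero exceeds the threshold —
#' operationally, `max(pp1, pp2) > threshold`, strictly.
#'
#' @param posteriors an `estro_posterior` tibble from [fit_all()].
#' @param chain chain index.
#' @param threshold posterior-probability cutoff (default 0.80).
#' @return character vector of selected `probe_id`s.
#' @export
call_chain <- function(posteriors, chain, threshold = 0.80) {
  check_posteriors(posteriors)
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  if (!chain %in% posteriors$chain) abort("chain index out of range.")
  posteriors |>
    filter(.data$chain == !!chain,
           pmax(.data$pp1, .data$pp2) > threshold) |>
    pull("probe_id")
}

#' Consensus across chains
#'
#' The intersection of per-chain selections: only probes significant in
#' every chain are reported, which damps Gibbs-sampling variation.
#'
#' @param per_chain_sets list of character vectors (one per chain).
#' @return character vector of probes present in all sets.
#' @export
consensus <- function(per_chain_sets) {
  if (!length(per_chain_sets)) abort("need at least one chain set.")
  Reduce(intersect, per_chain_sets)
}

#' Consensus association calls
#'
#' Applies the per-chain significance rule to every chain, counts in how
#' many chains each probe passes, marks as selected the probes passing in
#' all chains, and labels each selected probe's association pattern from
#' the chain-averaged posterior (see [classify_pattern()]).
#'
#' @inheritParams call_chain
#' @return tibble of class `estro_calls`: `probe_id`, `selected`,
#'   `max_pp` (chain-averaged max coefficient inclusion probability),
#'   `pattern` (`NA` for unselected probes), `chains_significant`.
#' @export
consensus_calls <- function(posteriors, threshold = 0.80) {
  check_posteriors(posteriors)
  n_chains <- length(unique(posteriors$chain))
  summary <- posteriors |>
    group_by(.data$probe_id) |>
    summarise(
      chains_significant =
        sum(pmax(.data$pp1, .data$pp2) > threshold),
      max_pp = max(mean(.data$pp1), mean(.data$pp2)),
      pp1 = mean(.data$pp1), pp2 = mean(.data$pp2),
      beta1_mean = mean(.data$beta1_mean),
      beta2_mean = mean(.data$beta2_mean),
      .groups = "drop"
    ) |>
    mutate(selected = .data$chains_significant == n_chains)
  summary$pattern <- NA_character_
  sel <- which(summary$selected)
  for (i in sel) {
    summary$pattern[i] <- classify_pattern(
      summary[i, c("pp1", "pp2", "beta1_mean", "beta2_mean")],
      threshold = threshold)
  }
  out <- summary |>
    mutate(probe_id = .data$probe_id) |>
    select("probe_id", "selected", "max_pp", "pattern",
           "chains_significant") |>
    arrange(match(.data$probe_id, unique(posteriors$probe_id)))
  class(out) <- c("estro_calls", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "n_chains") <- n_chains
  out
}

#' Bayesian FDR of a selection
#'
#' The estimated false discovery rate of a posterior-probability selection:
#' the mean of `1 - max_pp` over the selected probes. With all selected
#' probabilities near 1 the estimate approaches 0.
#'
#' @param max_pp numeric vector of the selected probes' posterior
#'   probabilities (each the max over the two coefficients), or an
#'   `estro_calls` tibble whose selected rows are used.
#' @return FDR estimate in `[0, 1]`; `NA` with a warning for an empty
#'   selection.
#' @export
bayes_fdr <- function(max_pp) {
  if (is.data.frame(max_pp)) {
    max_pp <- max_pp$max_pp[max_pp$selected]
  }
  if (!length(max_pp)) {
    warn("empty selection; Bayesian FDR undefined.")
    return(NA_real_)
  }
  if (any(max_pp < 0 | max_pp > 1)) abort("posterior probabilities must be in [0, 1].")
  mean(1 - max_pp)
}

#' Association pattern of a selected probe
#'
#' Labels the shape of a selected probe's association with the phenotype:
#' `linear_positive` / `linear_negative` when only the linear coefficient is
#' included (by the sign of its posterior mean), `quadratic_convex`
#' (U-shaped) / `quadratic_concave` (inverted U) when only the quadratic
#' coefficient is included (the basis sign convention makes a positive
#' quadratic coefficient convex), and `mixed` when both clear the
#' threshold.
#'
#' @param posterior a one-row data frame (or coercible list) with `pp1`,
#'   `pp2`, `beta1_mean`, `beta2_mean` — e.g. one probe's chain-averaged
#'   posterior.
#' @param threshold inclusion-probability cutoff (default 0.80).
#' @return one of `"linear_positive"`, `"linear_negative"`,
#'   `"quadratic_convex"`, `"quadratic_concave"`, `"mixed"`.
#' @export
classify_pattern <- function(posterior, threshold = 0.80) {
  p <- as.list(posterior)
  in1 <- p$pp1 > threshold
  in2 <- p$pp2 > threshold
  if (!in1 && !in2) {
    # fall back to the dominant coefficient when neither pp clears the
    # threshold on the chain average (a probe can be selected in every
    # chain yet have its averaged pp pulled just under it)
    if (abs(p$beta2_mean) > abs(p$beta1_mean)) in2 <- TRUE else in1 <- TRUE
  }
  if (in1 && in2) return("mixed")
  if (in2) return(if (p$beta2_mean > 0) "quadratic_convex" else "quadratic_concave")
  if (p$beta1_mean > 0) "linear_positive" else "linear_negative"
}

#' Overlap of selections across tissues
#'
#' Pairwise intersection sizes and the overall union of per-tissue probe
#' selections.
#'
#' @param sets_by_tissue named list of character vectors, one per tissue.
#' @return list with `pairwise` (tibble: `tissue_a`, `tissue_b`,
#'   `overlap`), `union_size`, and `per_tissue` (tibble of set sizes).
#' @export
overlap_counts <- function(sets_by_tissue) {
  if (length(sets_by_tissue) < 2L) abort("need at least two tissues.")
  if (is.null(names(sets_by_tissue)) || any(names(sets_by_tissue) == "")) {
    abort("`sets_by_tissue` must be a named list.")
  }
  nm <- names(sets_by_tissue)
  pairs <- utils::combn(nm, 2L)
  pairwise <- purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tibble(tissue_a = a, tissue_b = b,
           overlap = length(intersect(sets_by_tissue[[a]],
                                      sets_by_tissue[[b]])))
  }) |> bind_rows()
  list(
    pairwise = pairwise,
    union_size = length(unique(unlist(sets_by_tissue))),
    per_tissue = tibble(tissue = nm,
                        n_selected = lengths(lapply(sets_by_tissue, unique)))
  )
}

check_posteriors <- function(posteriors) {
  need <- c("probe_id", "chain", "pp1", "pp2", "beta1_mean", "beta2_mean")
  if (!is.data.frame(posteriors) || !all(need %in% names(posteriors))) {
    abort("`posteriors` must be a fit_all() result (probe_id, chain, pp1, pp2, ...).")
  }
  if (any(posteriors$pp1 < 0 | posteriors$pp1 > 1 |
          posteriors$pp2 < 0 | posteriors$pp2 > 1)) {
    abort("posterior probabilities must lie in [0, 1].")
  }
  invisible(posteriors)
}
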