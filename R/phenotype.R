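#' Average heat scores of the 28 experimental cows
#'
#' Loads the published per-cow average heat scores: 14 cows sacrificed at the
#' start of estrus (`day0`, including one extreme cow with a score of 1750)
#' and 14 sacrificed around mid cycle (`day12`). These are the phenotype
#' values the association analyses are built on and the worked example used
#' throughout the documentation.
#'
#' @return A tibble with columns `cow_id`, `group` (`day0`/`day12`) and
#'   `avg_heat_score`.
#' @export
#' @examples
#' heat_score_data()
heat_score_data <- function() {
  path <- system.file("extdata", "cow_heat_scores.tsv", package = "estrogram")
  read_phenotypes(path)
}

#' Average heat score over estrous cycles
#'
#' A cow's phenotype is the arithmetic mean of its per-cycle heat scores;
#' at least two consecutive cycles are required for the average to be
#' meaningful.
#'
#' @param cycle_scores numeric vector of non-negative per-cycle heat scores.
#' @param min_cycles minimum number of cycles required (default 2).
#' @param on_few what to do when fewer than `min_cycles` scores are supplied:
#'   `"error"` (default) or `"warn"`.
#' @return the arithmetic mean, a non-negative scalar.
#' @export
#' @examples
#' average_heat_score(c(100, 200))
average_heat_score <- function(cycle_scores, min_cycles = 2L,
                               on_few = c("error", "warn")) {
  on_few <- match.arg(on_few)
  if (!is.numeric(cycle_scores) || anyNA(cycle_scores) ||
      any(!is.finite(cycle_scores))) {
    abort("`cycle_scores` must be finite numbers with no missing values.")
  }
  if (any(cycle_scores < 0)) {
    abort("heat scores are non-negative by construction.")
  }
  if (length(cycle_scores) < min_cycles) {
    msg <- sprintf("fewer than %d cycle scores supplied (%d).",
                   min_cycles, length(cycle_scores))
    if (on_few == "error") abort(msg) else warn(msg)
  }
  mean(cycle_scores)
}

#' Flag outlying cows
#'
#' Flags cows whose average heat score is extreme within their group. The
#' default rule flags scores above `Q3 + 3 * IQR` (quartiles by linear
#' interpolation, computed per group); on the published table this flags
#' exactly the one cow with score 1750 and keeps the 405 cow. A `manual`
#' rule reproduces a narrative exclusion verbatim. A `zscore` rule flags
#' `|z| > z_cut` within group.
#'
#' @param phenotypes tibble with columns `cow_id`, `group`, `avg_heat_score`.
#' @param rule one of `"iqr"`, `"zscore"`, `"manual"`.
#' @param manual character vector of `cow_id`s to exclude (used by the
#'   `manual` rule, and applied on top of the other rules when supplied).
#' @param iqr_mult multiplier on the IQR (default 3).
#' @param z_cut z-score cutoff (default 3).
#' @return the input tibble with logical `excluded` and character
#'   `exclude_reason` columns.
#' @export
#' @examples
#' flag_outliers(heat_score_data())
flag_outliers <- function(phenotypes, rule = c("iqr", "zscore", "manual"),
                          manual = character(), iqr_mult = 3, z_cut = 3) {
  rule <- tryCatch(match.arg(rule),
                   error = function(e) abort("unknown outlier rule."))
  check_phenotype_table(phenotypes)
  out <- phenotypes |>
    group_by(.data$group) |>
    mutate(
      excluded = switch(
        rule,
        iqr = {
          q <- quantile(.data$avg_heat_score, c(0.25, 0.75), names = FALSE)
          .data$avg_heat_score > q[2] + iqr_mult * (q[2] - q[1])
        },
        zscore = {
          s <- sd(.data$avg_heat_score)
          if (!is.finite(s) || s == 0) rep(FALSE, n()) else
            abs(.data$avg_heat_score - mean(.data$avg_heat_score)) / s > z_cut
        },
        manual = rep(FALSE, n())
      ),
      exclude_reason = ifelse(.data$excluded, paste0(rule, " rule"), NA_character_)
    ) |>
    ungroup()
  if (length(manual)) {
    hit <- out$cow_id %in% manual
    out$excluded[hit] <- TRUE
    out$exclude_reason[hit] <- "manual exclusion"
  }
  out
}

#' Per-group phenotype summary
#'
#' Summarises retained (non-excluded) cows per group: count, mean, sample
#' standard deviation (n - 1 denominator), minimum and maximum. A group of
#' a single cow gets SD 0 with a warning.
#'
#' @param phenotypes tibble with `group` and `avg_heat_score`, optionally an
#'   `excluded` flag (excluded rows are dropped first).
#' @return tibble with one row per group: `group`, `n`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
#' @examples
#' heat_score_data() |> flag_outliers() |> summarize_heat_scores()
summarize_heat_scores <- function(phenotypes) {
  check_phenotype_table(phenotypes, need_cow_id = FALSE)
  if ("excluded" %in% names(phenotypes)) {
    phenotypes <- filter(phenotypes, !.data$excluded)
  }
  if (nrow(phenotypes) == 0L) abort("no retained cows to summarise.")
  if (any(table(phenotypes$group) == 1L)) {
    warn("a group has a single cow; its SD is reported as 0.")
  }
  phenotypes |>
    group_by(.data$group) |>
    summarise(
      n = n(),
      mean = mean(.data$avg_heat_score),
      sd = if (n() > 1L) sd(.data$avg_heat_score) else 0,
      min = min(.data$avg_heat_score),
      max = max(.data$avg_heat_score),
      .groups = "drop"
    )
}

check_phenotype_table <- function(phenotypes, need_cow_id = TRUE) {
  need <- c(if (need_cow_id) "cow_id", "group", "avg_heat_score")
  missing_cols <- setdiff(need, names(phenotypes))
  if (!is.data.frame(phenotypes) || length(missing_cols)) {
    abort(paste0("phenotype table must have columns: ",
                 paste(need, collapse = ", "), "."))
  }
  if (nrow(phenotypes) == 0L) abort("phenotype table is empty.")
  if (!is.numeric(phenotypes$avg_heat_score) ||
      anyNA(phenotypes$avg_heat_score)) {
    abort("`avg_heat_score` must be numeric without missing values.")
  }
  invisible(phenotypes)
}
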