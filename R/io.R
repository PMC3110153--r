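#' Read a phenotype TSV
#'
#' Expects columns `cow_id`, `group` and either `avg_heat_score` or
#' per-cycle columns `cycle_score_1..k` (averaged with
#' [average_heat_score()]).
#'
#' @param path TSV path.
#' @return phenotype tibble: `cow_id`, `group`, `avg_heat_score`.
#' @export
read_phenotypes <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("cow_id", "group") %in% names(tbl))) {
    abort("phenotype TSV needs `cow_id` and `group` columns.")
  }
  cyc <- grep("^cycle_score_", names(tbl), value = TRUE)
  if (!"avg_heat_score" %in% names(tbl)) {
    if (!length(cyc)) {
      abort("phenotype TSV needs `avg_heat_score` or cycle_score_* columns.")
    }
    tbl$avg_heat_score <- apply(as.matrix(tbl[cyc]), 1, function(v) {
      average_heat_score(v[!is.na(v)])
    })
  }
  check_phenotype_table(tbl)
  tbl
}

#' Read an expression matrix TSV
#'
#' Expects a `probe_id` column plus one numeric column per cow (or
#' cow:replicate). Duplicate probe ids are an error. Probes with more than
#' `max_missing` missing values are dropped; remaining missing cells are
#' mean-imputed with a warning.
#'
#' @param path TSV path.
#' @param max_missing maximum tolerated fraction of missing values per
#'   probe (default 0.2).
#' @return expression tibble.
#' @export
read_expression_matrix <- function(path, max_missing = 0.2) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(tbl)[1] != "probe_id") {
    abort("expression TSV must start with a `probe_id` column.")
  }
  dup <- tbl$probe_id[duplicated(tbl$probe_id)]
  if (length(dup)) {
    abort(paste0("duplicate probe ids: ", paste(unique(dup), collapse = ", ")))
  }
  # readr types all-missing columns as logical; treat them as numeric NA
  tbl[-1] <- lapply(tbl[-1], function(col) {
    if (is.logical(col) && all(is.na(col))) as.numeric(col) else col
  })
  M <- as.matrix(tbl[-1])
  if (!is.numeric(M)) abort("expression cells must be numeric.")
  frac_na <- rowMeans(is.na(M))
  if (any(frac_na == 1)) {
    abort(paste0("all-missing probes: ",
                 paste(tbl$probe_id[frac_na == 1], collapse = ", ")))
  }
  drop <- frac_na > max_missing
  if (any(drop)) {
    warn(sprintf("%d probes dropped (> %.0f%% missing).",
                 sum(drop), 100 * max_missing))
    tbl <- tbl[!drop, ]; M <- M[!drop, , drop = FALSE]
  }
  if (anyNA(M)) {
    warn(sprintf("%d missing cells mean-imputed.", sum(is.na(M))))
    for (g in which(rowSums(is.na(M)) > 0)) {
      M[g, is.na(M[g, ])] <- mean(M[g, ], na.rm = TRUE)
    }
    tbl[-1] <- as.data.frame(M)
  }
  check_expression_matrix(tbl)
  tbl
}

check_expression_matrix <- function(expression) {
  if (!is.data.frame(expression) || !"probe_id" %in% names(expression) ||
      ncol(expression) < 2L) {
    abort("expression matrix must have `probe_id` plus value columns.")
  }
  if (anyDuplicated(expression$probe_id)) {
    abort("expression matrix has duplicate probe ids.")
  }
  if (!all(vapply(expression[-match("probe_id", names(expression))],
                  is.numeric, TRUE))) {
    abort("expression values must be numeric.")
  }
  invisible(expression)
}

#' Analysis configuration
#'
#' One of the three study analyses: start-of-estrus cows only (`day0`),
#' mid-cycle cows only (`day12`), or both pooled (`day0_day12`, which
#' builds one basis from the pooled heat scores and gains power for
#' phase-independent associations).
#'
#' @param analysis `"day0"`, `"day12"` or `"day0_day12"`.
#' @param tissue free-text tissue label carried into outputs.
#' @param spec a [model_spec()].
#' @param threshold posterior-probability selection cutoff (default 0.80).
#' @param outlier_rule outlier rule for [flag_outliers()].
#' @param manual_exclude cow ids to exclude manually.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(analysis = c("day0", "day12", "day0_day12"),
                            tissue = "tissue", spec = model_spec(),
                            threshold = 0.80,
                            outlier_rule = "iqr",
                            manual_exclude = character()) {
  structure(list(analysis = match.arg(analysis), tissue = tissue,
                 spec = spec, threshold = threshold,
                 outlier_rule = outlier_rule,
                 manual_exclude = manual_exclude),
            class = "analysis_config")
}

#' Run the association pipeline for one tissue
#'
#' Orchestrates phenotype QC, cow subsetting per the analysis preset,
#' basis construction, per-probe model fits, consensus selection and
#' (optionally) gene-set enrichment, writing each stage's table plus a JSON
#' run manifest to `out_dir`. Reruns with the same inputs and manifest are
#' byte-identical.
#'
#' @param config an [analysis_config()].
#' @param phenotypes phenotype tibble (all cows; subsetting and outlier
#'   exclusion happen inside).
#' @param expression expression tibble for the tissue.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param annotation optional probe annotation for [map_probes_to_genes()].
#' @param collection optional [gene_set_collection()] for [enrich()].
#' @return list with `phenotypes`, `summary`, `basis`, `posteriors`,
#'   `calls`, `fdr`, `study_genes`, `enrichment` (NULL when no collection),
#'   `manifest`.
#' @export
run_pipeline <- function(config, phenotypes, expression, out_dir = NULL,
                         annotation = NULL, collection = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  message(sprintf("[phenotype] %d cows read", nrow(phenotypes)))
  phen <- flag_outliers(phenotypes, rule = config$outlier_rule,
                        manual = config$manual_exclude)
  phen <- filter(phen, !.data$excluded)
  keep_groups <- switch(config$analysis,
                        day0 = "day0", day12 = "day12",
                        day0_day12 = c("day0", "day12"))
  phen <- filter(phen, .data$group %in% keep_groups)
  message(sprintf("[phenotype] %d cows retained for %s",
                  nrow(phen), config$analysis))
  summary <- summarize_heat_scores(phen)
  basis <- build_basis(phen$avg_heat_score, degree = 2L)
  posteriors <- fit_all(expression, phen, spec = config$spec, basis = basis)
  message(sprintf("[model] %d probes fit in %d chains",
                  length(unique(posteriors$probe_id)),
                  config$spec$n_chains))
  calls <- consensus_calls(posteriors, threshold = config$threshold)
  fdr <- suppressWarnings(bayes_fdr(calls))
  message(sprintf("[selection] %d probes selected (Bayesian FDR %.3g)",
                  sum(calls$selected), fdr))
  study_genes <- NULL
  enrichment <- NULL
  if (!is.null(annotation)) {
    study_genes <- map_probes_to_genes(calls$probe_id[calls$selected],
                                       annotation)
    message(sprintf("[annotation] %d genes mapped", length(study_genes)))
    if (!is.null(collection)) {
      enrichment <- enrich(study_genes, collection)
      message(sprintf("[enrichment] %d sets tested, %d below EASE 0.10",
                      nrow(enrichment), sum(enrichment$pass_p)))
    }
  }
  manifest <- list(
    analysis = config$analysis, tissue = config$tissue,
    threshold = config$threshold, outlier_rule = config$outlier_rule,
    manual_exclude = config$manual_exclude,
    n_iter = config$spec$n_iter, n_burnin = config$spec$n_burnin,
    n_chains = config$spec$n_chains, seed = config$spec$seed,
    inclusion_prior = config$spec$inclusion_prior,
    n_cows = nrow(phen),
    n_probes = length(unique(posteriors$probe_id)),
    n_selected = sum(calls$selected),
    package_version = as.character(utils::packageVersion("estrogram"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(phen, file.path(out_dir, "phenotypes.tsv"))
    readr::write_tsv(summary, file.path(out_dir, "phenotype_summary.tsv"))
    readr::write_tsv(posteriors, file.path(out_dir, "posteriors.tsv"))
    readr::write_tsv(calls, file.path(out_dir, "calls.tsv"))
    if (!is.null(enrichment)) {
      readr::write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(phenotypes = phen, summary = summary, basis = basis,
       posteriors = posteriors, calls = calls, fdr = fdr,
       study_genes = study_genes, enrichment = enrichment,
       manifest = manifest)
}

#' Write simulated data to a directory
#'
#' Writes the phenotype, expression and truth tables of one simulation as
#' TSVs, the generator's file interface.
#'
#' @param sim list with `phenotypes`, `expression`, `truth` (see
#'   [simulate_phenotypes()], [simulate_expression()]).
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(phenotypes = file.path(dir, "phenotypes.tsv"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$phenotypes, paths["phenotypes"])
  readr::write_tsv(sim$expression, paths["expression"])
  readr::write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
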