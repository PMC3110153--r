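#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set id, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors of member genes; the
#'   descriptions are kept in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("no such GMT file: ", path))
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
    lines <- strsplit(readLines(path), "\t")
    desc <- setNames(vapply(lines, function(f) f[2], ""), names(sets))
  } else {
    lines <- strsplit(readLines(path), "\t")
    sets <- setNames(lapply(lines, function(f) unique(f[-(1:2)])),
                     vapply(lines, `[`, "", 1))
    desc <- setNames(vapply(lines, function(f) f[2], ""), names(sets))
  }
  structure(sets, descriptions = desc)
}

#' Assemble a gene-set collection over a background population
#'
#' Ties gene sets to the background universe (e.g. the deduplicated set of
#' orthologous genes represented on the array). Set members outside the
#' population are dropped with a warning, mirroring how over-representation
#' tools restrict annotation to the measured universe.
#'
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param population character vector of background gene ids (deduplicated).
#' @return list of class `gene_set_collection` with `sets` (restricted to
#'   the population) and `population`.
#' @export
gene_set_collection <- function(sets, population) {
  if (!length(sets) || is.null(names(sets))) abort("`sets` must be a named list.")
  population <- unique(as.character(population))
  if (!length(population)) abort("empty background population.")
  restricted <- lapply(sets, function(g) intersect(unique(g), population))
  dropped <- sum(lengths(lapply(sets, unique))) - sum(lengths(restricted))
  if (dropped > 0) {
    warn(sprintf("%d set members outside the population were dropped.", dropped))
  }
  structure(list(sets = restricted, population = population),
            class = "gene_set_collection")
}

#' Map selected probes to genes
#'
#' Translates probe-level calls to a deduplicated gene study set using a
#' probe annotation with specificity quality scores: only probes with
#' quality 1-4 (specific genome hits) carry annotation; quality 5-7 probes
#' (no or multiple hits) and probes without a gene are dropped.
#'
#' @param probes character vector of probe ids.
#' @param annotation tibble with columns `probe_id`, `gene_id`,
#'   `quality_score` (integer 1-7; `gene_id` may be `NA`).
#' @return character vector of unique gene ids.
#' @export
map_probes_to_genes <- function(probes, annotation) {
  need <- c("probe_id", "gene_id", "quality_score")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation))) {
    abort("annotation must have columns probe_id, gene_id, quality_score.")
  }
  hits <- annotation |>
    filter(.data$probe_id %in% probes,
           .data$quality_score >= 1, .data$quality_score <= 4,
           !is.na(.data$gene_id))
  unique(hits$gene_id)
}

check_contingency <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > K || k > n || K > N || n > N) {
    abort("inconsistent 2x2 table: need k <= min(K, n), K <= N, n <= N.")
  }
}

#' One-sided Fisher (hypergeometric upper tail)
#'
#' Probability of `k` or more study-set hits in a gene set under the
#' hypergeometric null: `P(X >= k)`, `X ~ Hypergeom(N, K, n)` — the
#' over-representation p-value.
#'
#' @param k study-set hits in the set.
#' @param K population genes in the set.
#' @param n study-set size.
#' @param N population size.
#' @return p-value in `(0, 1]`.
#' @export
fisher_one_sided <- function(k, K, n, N) {
  check_contingency(k, K, n, N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE score
#'
#' The conservative variant of the one-sided Fisher p-value used for
#' biological-theme discovery: one study-set hit is removed before the
#' test, so `ease_score(k, ...) = fisher_one_sided(max(k - 1, 0), ...)`.
#' Singleton evidence (`k = 1`) is thereby discounted to p = 1.
#'
#' @inheritParams fisher_one_sided
#' @return p-value in `(0, 1]`, always `>= fisher_one_sided(k, K, n, N)`.
#' @export
ease_score <- function(k, K, n, N) {
  check_contingency(k, K, n, N)
  fisher_one_sided(max(k - 1, 0), K, n, N)
}

#' Gene-set over-representation of a study set
#'
#' For each gene set, counts study-set hits against the background
#' population, computes the one-sided Fisher and EASE p-values, and
#' adjusts the EASE p-values across sets by Benjamini-Hochberg. Two report
#' tiers are flagged: an uncorrected discovery tier (`ease_p < p_cutoff`)
#' and an FDR tier (`bh_fdr < fdr_cutoff`).
#'
#' @param study_genes character vector of selected genes; genes outside the
#'   population are dropped with a warning.
#' @param collection a [gene_set_collection()].
#' @param p_cutoff uncorrected EASE threshold (default 0.10).
#' @param fdr_cutoff BH FDR threshold (default 0.20).
#' @return tibble sorted by `ease_p` (ties by `set_id`): `set_id`, `k`,
#'   `K`, `n`, `N`, `fisher_p`, `ease_p`, `bh_fdr`, `pass_p`, `pass_fdr`.
#' @export
enrich <- function(study_genes, collection, p_cutoff = 0.10,
                   fdr_cutoff = 0.20) {
  stopifnot(inherits(collection, "gene_set_collection"))
  study <- unique(as.character(study_genes))
  outside <- setdiff(study, collection$population)
  if (length(outside)) {
    warn(sprintf("%d study genes outside the population were dropped.",
                 length(outside)))
    study <- setdiff(study, outside)
  }
  if (!length(study)) {
    warn("empty study set; no enrichment computed.")
    return(tibble(set_id = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), fisher_p = numeric(),
                  ease_p = numeric(), bh_fdr = numeric(),
                  pass_p = logical(), pass_fdr = logical()))
  }
  N <- length(collection$population)
  n <- length(study)
  out <- purrr::imap(collection$sets, function(members, id) {
    K <- length(members)
    k <- length(intersect(members, study))
    tibble(set_id = id, k = k, K = K, n = n, N = N,
           fisher_p = fisher_one_sided(k, K, n, N),
           ease_p = ease_score(k, K, n, N))
  }) |> bind_rows()
  out |>
    mutate(bh_fdr = p.adjust(.data$ease_p, method = "BH"),
           pass_p = .data$ease_p < p_cutoff,
           pass_fdr = .data$bh_fdr < fdr_cutoff) |>
    arrange(.data$ease_p, .data$set_id)
}
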