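make_post <- function(pp1, pp2, beta1 = 1, beta2 = 0, chains = 1L) {
  # minimal posterior table: one probe per element of pp1, repeated chains
  n <- length(pp1)
  dplyr::bind_rows(lapply(seq_len(chains), function(ch) {
    tibble::tibble(probe_id = paste0("p", seq_len(n)), chain = ch,
                   pp1 = pp1, pp2 = pp2,
                   beta1_mean = rep_len(beta1, n),
                   beta2_mean = rep_len(beta2, n))
  }))
}

test_that("per-chain calls use a strict 0.80 threshold on the max pp", {
  post <- make_post(pp1 = c(0.85, 0.80, 0.0, 0.10),
                    pp2 = c(0.10, 0.80, 0.0, 0.95))
  sel <- call_chain(post, chain = 1)
  expect_setequal(sel, c("p1", "p4"))   # 0.85 in, 0.80 exactly is out
  expect_error(call_chain(post, chain = 9), "out of range")
  expect_error(call_chain(post, chain = 1, threshold = 1.5), "0, 1")
})

test_that("consensus is the intersection across chains", {
  expect_setequal(
    consensus(list(c("A", "B"), "A", c("A", "B"), "A", "A")), "A")
  expect_setequal(consensus(rep(list(c("X", "Y")), 5)), c("X", "Y"))
  expect_equal(consensus(list(character(), c("A"))), character())
  expect_error(consensus(list()), "at least one")
})

test_that("consensus calls require significance in every chain", {
  # probe p1 significant in both chains, p2 only in chain 1
  post <- dplyr::bind_rows(
    tibble::tibble(probe_id = c("p1", "p2"), chain = 1L,
                   pp1 = c(0.9, 0.9), pp2 = 0.1,
                   beta1_mean = 1, beta2_mean = 0),
    tibble::tibble(probe_id = c("p1", "p2"), chain = 2L,
                   pp1 = c(0.95, 0.5), pp2 = 0.1,
                   beta1_mean = 1, beta2_mean = 0))
  calls <- consensus_calls(post)
  expect_equal(calls$selected, c(TRUE, FALSE))
  expect_equal(calls$chains_significant, c(2L, 1L))
  expect_true(is.na(calls$pattern[2]))
  expect_equal(calls$pattern[1], "linear_positive")
})

test_that("the Bayesian FDR estimator is the mean selected miss probability", {
  expect_equal(bayes_fdr(c(0.90, 0.95)), 0.075)
  expect_equal(bayes_fdr(c(1, 1, 1)), 0)
  expect_warning(out <- bayes_fdr(numeric()), "empty selection")
  expect_true(is.na(out))
  expect_error(bayes_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("patterns follow coefficient inclusion and sign", {
  p <- function(pp1, pp2, b1, b2) {
    classify_pattern(list(pp1 = pp1, pp2 = pp2,
                          beta1_mean = b1, beta2_mean = b2))
  }
  expect_equal(p(0.95, 0.1, +2, 0), "linear_positive")
  expect_equal(p(0.95, 0.1, -2, 0), "linear_negative")
  expect_equal(p(0.1, 0.9, 0, +1), "quadratic_convex")
  expect_equal(p(0.1, 0.9, 0, -1), "quadratic_concave")
  expect_equal(p(0.9, 0.9, 1, 1), "mixed")
  # dominant-coefficient fallback keeps the labeling total on selected probes
  expect_equal(p(0.7, 0.5, 2, 0.1), "linear_positive")
  expect_equal(p(0.5, 0.7, 0.1, -2), "quadratic_concave")
})

test_that("raising the threshold never grows selections (monotonicity)", {
  s <- small_sim(n_probes = 80, frac_linear = 0.2, frac_quadratic = 0.1,
                 seed = 61, effect_scale = 1.2)
  post <- fit_all(s$expression, s$phenotypes, tiny_spec(seed = 62))
  prev_sets <- NULL
  prev_sel <- NULL
  for (th in c(0.5, 0.7, 0.8, 0.9, 0.97)) {
    sets <- lapply(1:5, function(ch) call_chain(post, ch, th))
    calls <- consensus_calls(post, th)
    sel <- calls$probe_id[calls$selected]
    if (!is.null(prev_sets)) {
      for (ch in 1:5) expect_true(all(sets[[ch]] %in% prev_sets[[ch]]))
      expect_true(all(sel %in% prev_sel))
    }
    prev_sets <- sets; prev_sel <- sel
  }
})

test_that("every selected probe receives exactly one pattern label", {
  s <- small_sim(n_probes = 100, frac_linear = 0.15, frac_quadratic = 0.15,
                 seed = 71)
  post <- fit_all(s$expression, s$phenotypes, tiny_spec(seed = 72))
  calls <- consensus_calls(post)
  expect_true(all(!is.na(calls$pattern[calls$selected])))
  expect_true(all(is.na(calls$pattern[!calls$selected])))
  expect_true(all(calls$pattern[calls$selected] %in%
                    c("linear_positive", "linear_negative",
                      "quadratic_convex", "quadratic_concave", "mixed")))
  # labels agree with planted truth for pure-signal probes
  m <- merge(calls[calls$selected, ], s$truth, by = "probe_id")
  lin <- m[m$class == "linear", ]
  expect_true(all(startsWith(lin$pattern, "linear") | lin$pattern == "mixed"))
  qu <- m[m$class == "quadratic", ]
  expect_true(all(startsWith(qu$pattern, "quadratic") | qu$pattern == "mixed"))
})

test_that("overlap counts report pairwise intersections and the union", {
  ov <- overlap_counts(list(a = c("A", "B"), b = c("B", "C")))
  expect_equal(ov$pairwise$overlap, 1L)
  expect_equal(ov$union_size, 3L)
  same <- overlap_counts(list(x = c("A", "B"), y = c("A", "B")))
  expect_equal(same$pairwise$overlap, 2L)
  expect_error(overlap_counts(list(a = "A")), "at least two")
  expect_error(overlap_counts(list(c("A"), c("B"))), "named")
  # a planted shared block makes its pair the largest overlap
  base <- paste0("g", 1:30)
  tissues <- list(DH = c(base[1:20], "u1"), VH = c(base[1:20], "u2"),
                  AM = c(base[25:30], "u3"), HC = c(base[28:30], "u4"))
  ov4 <- overlap_counts(tissues)
  top <- ov4$pairwise[which.max(ov4$pairwise$overlap), ]
  expect_setequal(c(top$tissue_a, top$tissue_b), c("DH", "VH"))
})
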