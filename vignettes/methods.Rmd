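---
title: "Methods: quantitative-phenotype association by spike-and-slab selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative-phenotype association by spike-and-slab selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`estrogram` regresses per-gene expression (two-color microarray M-values)
on a per-subject quantitative phenotype — the average heat score of dairy
cows — and calls genes whose expression depends linearly or quadratically
on it. This vignette documents the model, the choices that were genuinely
open, and what the synthetic-data calibration does and does not establish.

## Phenotype handling

A cow's phenotype is the arithmetic mean of heat scores from at least two
consecutive estrous cycles. The published table contains one cow whose
average (1750) dwarfs the rest (max 405); the original exclusion was a
narrative judgment call, not a formula. The default rule here —
score > Q3 + 3·IQR within group, quartiles by linear interpolation — was
chosen because it flags that cow and spares the 405 cow under all common
quartile conventions; a manual exclusion list reproduces any ad hoc
decision verbatim. Summaries use the sample (n − 1) standard deviation,
which reproduces the published 125.7 / 175.4. A single-cow group reports
SD 0 with a warning rather than NA, so downstream tabulation never breaks.

## The orthonormal basis

`build_basis()` orthonormalizes [1, x, x²] (QR of the Vandermonde matrix
after rescaling x to [−1, 1] for conditioning). Orthonormal rather than
merely orthogonal columns makes the two coefficients exchangeable under a
common slab prior — the prior penalizes both equally. Signs are fixed so
each column's leading coefficient is positive: P₁ is then a positive
multiple of centered x and a positive quadratic coefficient means a convex
(∪) trend, which is what the downstream pattern labels rely on. Fitted
values are invariant to affine rescaling of x, so whether heat scores are
standardized first is immaterial. Degree is fixed at 2 (linear +
quadratic); degree 3 remains available for comparison with older
third-order analyses but is less reliable at ~13–27 animals. The pooled
day0+day12 analysis builds one basis from the pooled scores; the separate
analyses build group-specific bases — which is why the pooled calls are
not the union of the separate calls.

## The per-gene model

For one gene, y_c = μ + γ₁β₁P₁(x_c) + γ₂β₂P₂(x_c) + e_c with
e ~ N(0, σ²). Priors: μ flat; β_k | slab ~ N(0, τ²) with τ² shared by the
gene's two coefficients (inverse-gamma(2, 1), prior mean 1, on the M-value
scale where planted effects of interest are order 1); γ_k ~ Bernoulli(π)
with π = 0.05; σ² ~ inverse-gamma(0.01, 0.01). The spike is an exact point
mass at zero, so pp_k — the post-burn-in frequency of γ_k = 1 — is a
genuine posterior probability that the coefficient is nonzero.

Choices worth recording:

* **Vague noise prior.** With a weakly informative σ² prior the prior
  scale dominates the residual sum of squares for near-noiseless genes at
  n ≈ 13–27, leaving a few percent shrinkage on perfectly identified
  coefficients. The vague inverse-gamma(0.01, 0.01) lets the data dominate
  σ², giving exact recovery (within Monte-Carlo error) on noise-free
  signals while behaving like the usual scaled-inverse-χ² posterior on
  noisy ones. An empirical-Bayes alternative (`estimate_noise_prior()`,
  moderating variances across genes via a scaled-F fit) is available when
  genes should share variance information.
* **π = 0.05.** Small prior inclusion keeps the null selection rate of the
  0.80-consensus rule well under 1% (measured: ~0.02–0.05% on 5,000-probe
  null panels at 27 cows), the operational counterpart of the selection
  rule's advertised FDR control.
* **Collapsed indicator updates.** Each Gibbs sweep updates μ, then
  (γ_k, β_k) jointly with β_k marginalized out of the indicator draw, then
  σ² and τ². Marginalization avoids the absorbing states a naive sampler
  has when β_k is currently near zero. τ² is updated from the currently
  included coefficients and reverts to its prior when none are included.
  Validity is checked in the test suite against an independent
  Metropolis sampler with β integrated out analytically (total-variation
  distance of indicator-state frequencies < 0.02) and against the
  closed-form conjugate posterior when indicators are clamped.
* **Numerical floors.** σ² is floored at 1e−8 so noise-free fixtures
  remain stable; the floor is far below any realistic M-value residual
  variance.
* **Reproducibility.** The RNG stream for each (probe, chain) is derived
  by hashing (master seed, probe id, chain index), so results are
  invariant to probe subsetting, column order and scheduling; chains are
  genuinely independent replicates.
* **Technical replicates.** Dye-swap replicates are averaged per cow
  before fitting. The replicate-as-random-effect alternative adds one
  variance component the data barely inform at 2 replicates; averaging is
  the variance-stabilizing default and keeps the per-gene model conjugate.

Defaults of 5 chains × 10,000 iterations (5,000 burn-in) match the stated
operating point; the calibration tests and the acceptance script run
2,000/1,000, at which pp estimates carry Monte-Carlo SE ≈ 0.013 near the
0.80 threshold — visible as borderline probes dropping out of single
chains, which is exactly what the all-chain consensus rule is for.

## Selection, FDR, patterns

A probe is significant in a chain iff max(pp₁, pp₂) > 0.80, strictly
(probes at exactly 0.80 are not selected), and selected iff significant in
every chain. The Bayesian FDR estimate of a selection is mean(1 − max pp)
over selected probes; on synthetic panels with strong signals the
empirical FDR against planted truth sits at or below this estimate. Pattern
labels use the chain-averaged posterior: only the linear (quadratic)
coefficient included → linear with slope sign (quadratic
convex/concave by the sign of the coefficient under the basis sign
convention); both included → `mixed`, reported rather than forced into a
pure class. A probe can pass the per-chain rule in every chain while its
chain-averaged pp sits marginally under the threshold; classification then
falls back to the dominant coefficient so every selected probe gets
exactly one label.

## Enrichment

Over-representation only (one-sided): Fisher's exact p is the
hypergeometric upper tail P(X ≥ k); the EASE score is the same tail with
one study-set hit removed, max(k − 1, 0), which sends singleton hits to
p = 1. The background population is the user-supplied deduplicated gene
universe (e.g. orthologous genes represented on the array); set members
outside it are dropped with a warning. Probes map to genes through a
quality-scored annotation (quality 1–4 = specific hits are kept; 5–7 =
none/multiple hits carry no annotation). Both an uncorrected EASE < 0.10
tier (theme discovery) and a Benjamini–Hochberg FDR < 20% tier are
reported, since either convention may be wanted; BH is used because the
original FDR procedure behind such cutoffs is typically unnamed.

## The synthetic-data generator

The generator emulates the study design: 13 + 14 cows in two groups, heat
scores from a normal left-truncated at zero per group, thousands of probes
of which a small fraction carries a planted linear or quadratic dependence
on the orthonormal basis, gene-specific residual variances, and two
dye-swap technical replicates per cow. The configured group moments
(defaults 178.4/125.7 and 244.7/175.4) are the **post-truncation** mean/SD:
the pre-truncation parameters are solved numerically so the simulated
scores actually have the published moments — naive truncation of
N(178.4, 125.7) at zero would inflate the mean by about 20 points.

Remaining generator defaults, chosen once as field-realistic and not
revisited: residual variances σ²_g ~ inverse-gamma(shape 4, scale 0.4)
(mean 0.133, i.e. residual SD ≈ 0.3–0.4, the range typical of normalized
two-color M-values); planted |β| uniform on [0.5, 1.5] × `effect_scale`
with random sign, `effect_scale` = 2 as the strong-signal operating point;
5% linear + 5% quadratic probes ("a minority"); quadratic-truth probes get
β₁ = 0 so the pattern ground truth is unambiguous.

What the generator does **not** emulate: raw two-color intensities, dye
bias, spatial artifacts, probe cross-hybridization, correlated expression
across genes, and heavy-tailed or outlying M-values. Passing calibration
on synthetic panels therefore shows the selection machinery is correct and
calibrated under the stated noise model, not that real arrays meet that
model; on real data the normalization upstream of the M-values carries
that burden. The published per-tissue probe counts cannot be reproduced
without the deposited arrays and the original program; the package's
claims are the property-based ones.

## Problem sizes

The test suite validates the sampler against closed forms on 27-cow
fixtures, runs the null calibration at 5,000 probes × 5 chains × 2,000
iterations, and the power/FDR check at 1,000 probes with 10% planted
signals at `effect_scale` 2 (measured: null consensus selection ~0.02%,
power ~0.9, empirical FDR 0, Bayesian FDR estimate < 1%). Exhaustive
Fisher/EASE verification covers every 2×2 table with population size
N ≤ 60 against direct pmf summation.

## Known limitations

* The original model's exact random-effect structure and hyperparameters
  are not public; this implementation is compatible-with, not
  identical-to, and probe counts should not be compared across the two.
* Marginal pp per coefficient is computed and the "at least one
  coefficient" rule applied afterwards; a joint version would differ
  slightly for strongly correlated coefficients (the orthonormal basis
  keeps that correlation small).
* The Bayesian FDR estimator inherits the model's calibration: under
  misspecified noise it can be optimistic, which is why the synthetic
  check compares it against truth-label FDR.
* One sampler sweep is O(n) per gene; the whole-panel cost is linear in
  probes × chains × iterations, single-threaded. Per-(probe, chain) seeding
  makes parallelization safe if ever needed.
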