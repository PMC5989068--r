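---
title: "Methods: meta-analysis of case-control gut microbiome surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of case-control gut microbiome surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Case-control 16S rRNA gene surveys of colorectal cancer (CRC) disagree
about which gut bacteria mark the presence of tumors. Individual cohorts
are small, processed with different primers and pipelines, and the
taxa enriched in carcinoma patients are *patchy*: a given patient carries
some but rarely all of them. `crcmeta` implements the analysis pattern that
addresses this: analyze every cohort separately on a harmonized taxon
namespace, reduce each taxon in each cohort to a median-dichotomized 2x2
odds ratio, pool the per-cohort log-ORs with a random-effects model, and
evaluate multivariable Random Forest classifiers within and across cohorts.
Because the underlying sequence data are controlled-access, the package
ships a synthetic multi-cohort generator with ground truth so every stage
is testable end to end.

# The data model

A `study_table` is one cohort: a samples-by-features count matrix
(orientation fixed, samples in rows) plus per-sample metadata
(`diagnosis` in {control, adenoma, carcinoma}, `site` in {feces, tissue},
subject id, matched flag, 16S region). `harmonize()` reindexes taxon-level
cohorts onto the union of taxon labels with explicit zeros; matching is
exact-string on the classifier label, because pooling across cohorts is
only meaningful for identical labels. OTU tables are never harmonized:
OTUs are defined per cohort. Samples with zero total counts are rejected
at read time; the command-line reader additionally drops samples below a
`min-total` threshold (default 100 reads, making the usual low-coverage
exclusion explicit rather than silent).

# Per-cohort statistics

**Alpha diversity.** Richness S, Shannon H (nats), and Pielou evenness
J = H / ln S (J = 0 when S = 1, so single-taxon samples are defined and
minimally even). H and J are invariant to scaling counts, so no
rarefaction is applied by default; a seeded common-depth subsampling
option exists for users who want it. Severity trends are tested with a
linear mixed model: per-study Tukey-ladder power transform (lambda on a
grid of -5..5 by 0.05, maximizing Shapiro-Wilk W) then Z-scoring, followed
by `value ~ severity + region + (1 | study)` with severity coded 0/1/2 and
a `(1 | subject)` term for tissue, where individuals are sampled twice.
p values are Wald normal approximations on the severity coefficient.

**Diversity odds ratios.** Within a cohort, the metric's median is taken
over the two compared groups only; by default a sample *below* the median
counts as exposed, so OR > 1 reads "low diversity associates with
disease". The literal above-median convention is available via the
`direction` flag; flipping it inverts the OR exactly.

**Community structure.** Bray-Curtis dissimilarity
(sum |x - y| / sum (x + y)) on relative abundances, and a one-way
permutation PERMANOVA: the pseudo-F comes from the sums-of-squared-distance
decomposition, and p = (1 + #{F_perm >= F_obs}) / (1 + n_perm), so p is
never zero and has resolution 1/(n_perm + 1). Matched tissue cohorts
restrict permutations to within-subject swaps, the natural exchangeable
unit for paired designs.

# The core biomarker statistic

For each taxon in each cohort, a sample is *exposed* when its relative
abundance is strictly above the within-cohort median (ties unexposed).
The 2x2 exposure-by-disease table gives OR = ad/bc with the Woolf standard
error sqrt(1/a + 1/b + 1/c + 1/d); the Haldane-Anscombe 0.5 correction is
applied only when a zero cell is present, and a Pearson chi-square (1 df,
no continuity correction) is always computed on the uncorrected table.
Tables with an empty exposure margin are degenerate and excluded; a taxon
needs non-degenerate tables in at least two cohorts to be pooled.

Pooling is DerSimonian-Laird: fixed weights w = 1/se^2 give Q; the
between-study variance is tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 /
sum w)); random-effects weights 1/(se^2 + tau^2) give the pooled log-OR,
its standard error, and a two-sided Wald p. Benjamini-Hochberg is applied
to the pooled p values across all pooled taxa within one (site,
comparison); a taxon is a biomarker when its adjusted p falls below 0.05.
The per-cohort chi-square p values are retained and emitted alongside, as
the per-study convention reports them, but selection uses the pooled p —
significance is a cross-study claim.

# Classification

The Random Forest is implemented in compiled code inside the package
(no forest implementation is assumed in the environment): 500 bagged CART
trees, Gini splits, mtry = floor(sqrt(p)) candidate features per node,
grown to purity, class probabilities averaged over trees, and
permutation-based mean-decrease-in-accuracy (MDA) importances computed on
the out-of-bag samples. All fits are seed-deterministic through R's RNG.

Cross-validation is stratified k-fold (10 for fecal cohorts, 5 for tissue,
falling back to 2 with a warning when k exceeds the smallest class — the
rule used for the smallest published cohort). Out-of-fold probabilities
are pooled into a single ROC per repeat rather than averaging per-fold
AUCs, which is unstable for cohorts of a dozen samples; the per-fold
alternative was considered and rejected for that reason. The OTU regime
repeats the whole CV 100 times and reports the mean AUC. Cross-study MDA
rankings Z-score the MDA vector within each cohort and rank taxa by mean
Z. Model comparisons across cohorts use a one-tailed paired t test on
per-cohort AUCs (identical vectors give t = 0, p = 0.5; a zero-variance
positive difference is flagged degenerate with the limit p = 0), plus the
mean percent AUC difference.

Transfer evaluation trains on each cohort in full and scores every other
cohort. For the significant-taxa regime the panel scored against a given
test cohort is selected by pooled meta-analysis *excluding that cohort*.
The design goal here is no test-study leakage; selection from the training
cohort alone was considered but rejected: single-cohort pooling is
undefined (k >= 2 is required) and within-cohort selection has no power at
realistic sizes. When nothing survives BH, the eight smallest pooled p
values are used (eight being the published panel size), so a model can
always be trained.

# The synthetic world

`generate_study()` emulates what sequence processing hands to the
analysis. Per sample: depth ~ NegBin(mean 10,000, dispersion 5) — a
realistic inter-sample depth spread; upstream sequence processing does not
fix one. The community draw is a *generalized Dirichlet*: independent gammas
with a common shape (`base_concentration / n_taxa`, default 150/200 =
0.75, i.e. log-abundance spread ~1.5) and Zipf (1/rank) means, normalized.
A strict Dirichlet was tried first and rejected: it ties a taxon's
overdispersion to its mean abundance, which forces rare taxa to be absent
from half the samples at any realistic concentration and makes
moderately-abundant taxa so noisy that the abundance shifts needed for a
detectable odds ratio displace enough case mass to make abundant null taxa
spuriously significant. Decoupling dispersion from abundance is also the
more realistic description of deep-sequenced stool data.

Structure on top of the base draw:

- **Study effects**: per-cohort, per-taxon multiplicative effects
  exp(N(0, 1)) make cohorts compositionally distinct (pooled cohorts
  separate by study label with PERMANOVA p <= 0.001 — the reason the
  analysis is per-cohort). Disease-associated taxa are exempt: the
  emulated world has a signal that is consistent across cohorts riding on
  idiosyncratic backgrounds, which is what makes a small consistent panel
  transfer between cohorts better than full-community models.
- **Enriched taxa** (default: four taxa at Zipf ranks 60/70/80/90, rare as
  the mouth-associated CRC taxa are in stool): present in any sample only
  with probability 1 - patchiness (default patchiness 0.3), independent of
  diagnosis — patchy carriage; when present in a carcinoma sample their
  abundance is shifted. The effect size is stated on the *log odds-ratio
  scale* (default 1.0): `dichotomized_shift()` solves the generator's own
  zero-inflated log-gamma model for the abundance shift whose
  median-dichotomized log-OR equals the stated value (falling back to a
  logistic-scale approximation when patchiness >= 0.5 puts the median on
  the zero mass). Realized pooled log-ORs recover roughly 0.85-0.95 of the
  stated value; the residual attenuation (sampling noise, between-study
  heterogeneity) is part of the world, not corrected away.
- **Protective taxa** (default: two taxa at ranks 5 and 8, abundant and
  consistently present, log-OR -0.5): reduced abundance in cases, no
  patchiness.
- **Adenomas** receive all effects attenuated by 0.25: adenoma contrasts
  should come out near-null, as published.
- **Matched tissue cohorts**: the three default tissue cohorts with
  exactly equal control/case counts are generated as subject-paired
  designs.

Default cohort ids, sizes, and 16S regions follow the published Tables
(8 fecal cohorts, 1,737 samples; 7 tissue cohorts, 492 samples).

## What a green test does and does not establish

The generator reproduces the *statistical geometry* the analysis assumes —
cohort-level composition shifts, patchy rare enrichment, consistent
protection, near-null adenomas — not real biology: no phylogenetic
correlation among taxa, no sequence-level artifacts (chimeras, primer
bias), no covariates (age, FIT), and single-taxon AUCs of the default
enriched taxa land near 0.65-0.70, somewhat higher than the published
~0.55-0.59. Green acceptance tests therefore establish that the pipeline's
statistics are correct and that the published qualitative contrasts follow
from the assumed structure; they do not re-derive the published numerical
ORs or AUCs, which require the original controlled-access data (those
headline values appear in documentation only as anchors).

# Numerical choices and degenerate inputs

- Ties at the dichotomization median are unexposed (strict inequality).
- Haldane-Anscombe only on zero cells; chi-square always uncorrected
  (continuity correction available nowhere, matching the cited
  epidemiology tooling's default class).
- BH is the exact step-up min-over-suffix form, capped at 1.
- tau^2 is clamped at 0.
- PERMANOVA never returns p = 0; permutation count sets the resolution.
- The Tukey ladder shifts non-positive inputs by min + epsilon before
  searching, so log/negative-power branches are defined; constant vectors
  are an error everywhere (no transform, Z-score, or MDA Z is defined).
- AUC uses midranks, so constant scores give exactly 0.5.
- `compare_models` on identical vectors returns p = 0.5; zero-variance
  non-zero differences are flagged degenerate.
- Seeds: one global seed expands deterministically into per-stage,
  per-study streams (`derive_seed`), all below 2^31, so any stage can be
  reproduced in isolation.

# Compute scaling in the test suite

Simulation-heavy acceptance checks state 50-200 seeds at full cohort
sizes; on one CPU that exceeds the suite's budget for the Random Forest
criteria, so the qualitative-contrast suite runs cohorts at 50% scale with
10 seeds (directions and thresholds unchanged, reductions noted inline in
the tests). Biomarker parameter recovery runs at full size with the stated
50 seeds; PERMANOVA calibration runs the stated 500 simulations.

# Known limitations

- The generator has no direct alpha-diversity effect dial, so the
  diversity-OR machinery is validated by null coverage and hand-computed
  tables, not by recovering a tuned evenness OR.
- Realized effect sizes slightly undershoot their stated log-OR values;
  tests assert recovery of the truth labels, not the exact magnitudes.
- The mixed-model p values are Wald approximations.
- `region` is confounded with cohort in the defaults (as in the real
  tables); the fixed region term is retained for fidelity but is only
  weakly identified, which mirrors the original design's limits.
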