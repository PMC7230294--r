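---
title: "Paired PLS-DA ensembles for two-state targeted metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired PLS-DA ensembles for two-state targeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocpls)
options(vocpls.quiet = TRUE)
```

`vocpls` analyses paired two-state targeted metabolomics: each patient
contributes one in-crisis (IC) and one steady-state (OC) sample of the same
matrix (plasma or red blood cells), and the question is which metabolites of
a fixed quantitative panel discriminate the two states, and how reliably a
supervised model separates them on held-out patients. This vignette is the
package's account of the model, its parameters, the numerical choices, and
what the synthetic benchmarks do and do not establish.

## The data model

A *panel* fixes the metabolite catalogue: identifier, biochemical class, and
the assay's lower/upper limits of quantitation (LLOQ/ULOQ, µM). The bundled
default panel has the composition of a 188-metabolite targeted kit
(1 free carnitine, 39 acyl-carnitines, 1 hexose, 21 amino acids, 21 biogenic
amines, 14 lysophosphatidylcholines, 38 + 38 phosphatidylcholines, 15
sphingomyelins). The class counts are the kit's; the individual identifiers
and quantitation limits are plausible synthetic stand-ins, since per-analyte
vendor limits are not reproduced (validating identities against the real kit
catalogue is out of scope).

A *paired dataset* is a wide samples × metabolites grid of non-negative
concentrations plus a parallel grid of censoring flags (`OK`, `BELOW_LLOQ`,
`ABOVE_ULOQ`) derived by comparing each value against the panel limits.
Missing cells are a validation failure, not a supported state: the
quantitation filter reasons about out-of-range counts, and a silent `NA`
path would blur that contract. Pairing is enforced structurally — a dataset
that lacks either state for any patient does not construct.

## Quantitation-range filter with chi-squared rescue

A metabolite is excluded when more than 20% of its values fall outside the
quantitation range (the rule is strictly greater-than: exactly 20% is kept).
Exclusion risks discarding genuinely discriminant metabolites whose
censoring is itself state-dependent — a metabolite pushed below the LLOQ
only during crisis is informative. So each candidate for exclusion gets a
Pearson chi-squared test (2×2: in/out of range × IC/OC, 1 df, no continuity
correction) and is *rescued* when p < 0.05. Keeping on significance is an
interpretation: a significant association means the censoring pattern tracks
crisis status, which is exactly the discriminant signal the rescue is meant
to protect. Degenerate tables (a zero margin, e.g. no out-of-range values)
return statistic 0 and p = 1, and a log note flags expected cell counts
below 5, where the asymptotic reference is shaky.

Out-of-range values of retained metabolites must enter the model somehow.
They are imputed deterministically — `BELOW_LLOQ` as LLOQ/2, `ABOVE_ULOQ` as
ULOQ — the common fixed-value convention for left-censored targeted data.
A probabilistic imputation would add variance without changing what the
downstream ranks respond to; determinism keeps reruns bit-identical. Flags
are preserved on the filtered dataset as the imputation record. No
multiplicity correction is applied across rescue tests; with ~35 candidate
tests per study-sized run this is deliberately permissive, in keeping with
the rescue's protective purpose.

## Paired PLS-DA

The supervised model is PLS1 regression of the class code (IC = 1, OC = 0)
on the unit-variance-scaled concentration table, two latent variables by
default (the score plots live in a plane, and a third component adds little
for n = 40 pairs). Scaling uses the sample standard deviation (n − 1) and is
always estimated on the training samples only.

"Paired" is honoured in two independent ways, both available:

* **Pair-respecting resampling** (always on): no split — outer, training,
  or validation — ever separates a patient's two samples.
* **Multilevel decomposition** (default on, switchable via
  `multilevel = FALSE`): before scaling, each value is replaced by its
  within-patient deviation re-centred at the training grand mean,
  `x − x̄(patient) + x̄(grand)`. This removes between-patient variation, the
  dominant nuisance in crossover-like designs. Held-out samples are
  decomposed with their own within-pair means (self-contained) plus the
  *training* grand means, so no information leaks from evaluation data.

Both interpretations of paired PLS-DA exist in the literature; the package
makes the choice explicit rather than anointing one, and the benchmarks run
with the multilevel default.

NIPALS details, fixed for reproducibility: weights `w_a ∝ X_a'y_a`
normalised to unit length; scores `t_a = X_a w_a`; loadings
`p_a = X_a't_a / t_a't_a`; y-loading `q_a`; deflation of X and y. The
component sign is indeterminate, so each `w_a` is flipped to make its
largest-magnitude coordinate positive. Deflation stops early (logged) when
`t_a't_a < 1e-12`. Prediction is `ŷ = ȳ_train + Σ_a q_a t_a(new)`; a sample
at the training mean scores exactly at the class midpoint.

Two per-metabolite summaries feed variable selection:

* **VIP**, with the standard normalisation `Σ_j VIP_j² = p`; VIP ≥ 1 marks
  a variable as contributing more than average.
* **Oriented loading**: the first-component X-loading `p_1`, sign-flipped so
  that positive means elevated in crisis. The y-relationship could equally
  be read from `w_1`; `p_1` is chosen because it describes how X itself
  loads on the discriminant direction, and the choice is documented rather
  than load-bearing (the two are nearly collinear in practice).

## Scoring: AUROC and its p-value

AUROC is computed in Mann–Whitney form from rank sums (ties count ½), so it
is invariant under monotone transforms of the scores. Its two-sided p-value
against AUROC = 0.5 uses, in order of preference: the exact permutation
distribution of the rank sum (dynamic programming over subset rank sums,
cached per class-size pair) when scores are untied and both classes have at
most 12 members — the pipeline's validation and test sets are 10 vs 10 and
always hit this path; a seeded 10,000-draw Monte-Carlo permutation test when
ties intrude at small n; and a normal approximation with tie correction and
continuity correction otherwise. The method used is recorded in the result.
The continuity correction matters: without it the approximation deviates
from the exact tail by up to ~0.03 at 10 vs 10, with it by well under 0.02.

An unsupervised PCA check (`pca_scores()`, column-centred, unit-variance
scaled) reports sample coordinates and explained-variance fractions, and
flags potential outliers (|coordinate| > 3 SD on a reported component) —
it never removes samples automatically, since outlier exclusion is a
wet-lab judgement.

## The ensemble

The outer split assigns `min(30, ceiling(3n/4))` pairs to
training-validation and the remainder to a held-out test set — 30/10 at 40
pairs, 30/9 at 39 — by a seeded shuffle, with both sides then sorted so that
downstream indexing is canonical. Within the training-validation pairs, the
C(30, 20) = 30,045,015 possible training subsets are never materialised:
the k-subsets are generated on demand by lexicographic unranking
(combinadic), bijective over ranks, and sampled systematically every
`stride` ranks from offset 0. At the study scale the default stride is
exactly 1287, giving 23,345 models (1287 × 23,345 = 30,045,015); for other
design sizes the stride auto-scales as `max(1, floor(total / target_models))`.
The lexicographic order and zero offset are conventions, stated here because
any systematic sample of a combination sequence needs both pinned down to be
reproducible.

Each sampled model is fitted on its 20 training pairs only (multilevel
grand means and scaler included) and scored on the 10 validation pairs.
*Best models* are those with validation AUROC ≥ 0.95; models with AUROC
below 0.5 are not flipped — the ensemble treats AUROC as a one-directional
classifier score. Each best model is re-scored on the outer test pairs, and
the ensemble passes when the median test AUROC is at least 0.8 with median
p at most 0.05.

Aggregation across best models needs a sign convention, because each fit's
components are individually sign-indeterminate: component 1 of every best
model is oriented so its y-loading is positive (positive loading ⇔ elevated
in crisis), and higher components are aligned to the lowest-rank best model
by the sign of the loading-vector inner product. Medians are then marginal:
per metabolite for VIP and oriented loading, per training-validation sample
for the latent coordinates (every best model projects all 60
training-validation samples through its own preprocessing). Selection takes
metabolites with median VIP ≥ 1, direction read from the median loading's
sign.

## The synthetic generator

`simulate_dataset()` draws, per metabolite and patient, a bivariate pair of
log-concentrations: a shared patient intercept contributes fraction ρ of the
log-scale variance (default within-patient correlation 0.5 — the value that
makes pairing matter without dominating), state noise the rest, and the
metabolite's log-fold effect shifts the IC mean. Concentrations are the
exponentials — positive and right-skewed, as concentration data are — and
censoring flags follow from the panel limits. Default baselines put each
metabolite at the geometric midpoint of its quantitation range with a
per-metabolite log-SD drawn once from U(0.2, 0.6); these are stated
assumptions, not values calibrated to any measured dataset, which reports no
variance or correlation estimates to calibrate against. Seeding is keyed:
every metabolite derives its own stream from the master seed and its
identifier, so extending a panel leaves existing metabolites' draws
untouched.

Three bundled scenarios mirror the study shape (default panel; 39 pairs
plasma / 40 pairs rbc):

* `scenario_study()` — 60 discriminant metabolites, |log-fold effect| ~
  U(0.2, 0.8) with mixed signs (a signature size of ~60 matches the scale of
  reported two-state signatures), plus 35 poorly quantified null metabolites
  whose baseline sits at the LLOQ so the quantitation filter removes them,
  leaving 153 measured metabolites;
* `scenario_strong_effect()` — as above with effects U(0.5, 0.8); the
  parameter-recovery benchmark;
* `scenario_null()` — no effects; the calibration benchmark.

What the generator does **not** emulate: acquisition noise structure, batch
and plate effects, inter-metabolite correlation beyond the shared patient
intercept, heavy-tailed or bimodal concentration distributions, and
class-dependent censoring other than what planted effects induce. Passing
benchmarks therefore show the machinery is correct and well calibrated under
a lognormal paired model — not that any particular real dataset will reach
the same performance.

## Benchmarks and problem sizes

The test suite and `scripts/acceptance.R` run the strong-effect recovery at
2,000 sampled models (stride auto-scaled from C(30,20)) and the null
calibration at 2,000 models × 3 seeds — sizes chosen so the full suite
completes in a few minutes on one core while the model count stays large
enough for stable medians. On the strong-effect scenario the selected set
recovers ≥ 80% of planted metabolites with ≤ 10% of nulls selected and
median test AUROC ≥ 0.8 (in practice ~0.98 sensitivity and ~0.01 false
selection). On the null scenario the pooled median validation AUROC over the
three seeds lies in [0.35, 0.65] and the best-model fraction stays below 5%
(in practice well below 1%); pooling across seeds is used because a single
outer split induces strong correlation among its models, making a
single-seed median noisy without being informative.

## Numerical and serialization choices

* Binomial coefficients are computed by the exact multiplicative scheme
  (every intermediate is itself a binomial coefficient, so divisions are
  exact) with a guard at 2^53, the integer-exact range of doubles; all
  study-scale counts sit far inside it.
* Concentration CSVs are written with 17 significant digits and parsed with
  the base R reader, so write → read round-trips values bit-for-bit.
* Exact p-value distributions are cached per class-size pair; the
  Monte-Carlo tie fallback derives its seed from the data, keeping repeated
  calls identical without touching the caller's RNG state.
* All pipeline randomness (outer split, generator) flows from explicit
  seeds; rerunning a manifest reproduces every table and figure.

## Limitations

Two-class discrimination only (no multi-class, no sparse or orthogonal PLS
variants). The rescue rule's significance direction and the loading
definition are documented interpretations of ambiguous conventions. The
exact p-value floor at 10 vs 10 validation pairs is 2/C(20,10) ≈ 1.1e-5, so
reported median p-values saturate there for strongly separable data.
Selection thresholds (VIP ≥ 1, best-model AUROC ≥ 0.95) are field
conventions, configurable but not tuned by the package.
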