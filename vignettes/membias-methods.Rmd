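---
title: "Methods: scoring emotional memory bias and testing its mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring emotional memory bias and testing its mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membias)
```

## The analysis problem

Randomized heart-rate-variability (HRV) biofeedback trials train one arm to
amplify heart-rate oscillations through slow paced breathing (Osc+) and an
active control arm to suppress them (Osc−). A mechanistic question in such
trials is whether the intervention shifts *implicit* emotion regulation —
observable as a memory bias favoring positive over negative material — and
whether that shift runs through strengthened resting amygdala–mPFC
functional connectivity. `membias` implements the full statistical path
from raw behavioral tables to that answer:

1. **Recognition scoring.** Remember/Know/New responses to 36 studied and
   36 lure pictures (12 per valence per status) become per-participant
   hit, false-alarm and corrected-recognition rates per valence
   (`compute_recognition_rates()`). An item is "called old" when the
   response is Remember or Know, the standard Remember/Know convention.
2. **Recall scoring.** Two coders independently match free-recall
   descriptions to studied pictures, coding each (participant, picture)
   unit 0, 1, or occasionally 2. Reliability is Krippendorff's alpha with
   a unit-resampling bootstrap CI (`krippendorff_alpha()`,
   `bootstrap_alpha_ci()`); discrepancies are enumerated and resolved by a
   deterministic rule (`reconcile_coders()`), and codes are summed into
   per-valence counts (`tally_recall()`).
3. **Bias composite.** The positive emotional memory bias is
   `(z_FA_pos − z_FA_neg) + (z_Recall_pos − z_Recall_neg)`, built from
   final-week false alarms (a retrieval-criterion measure; hit rates
   confound accuracy with criterion) and final-week recall counts
   (`compute_bias_scores()`).
4. **Mediation.** A single-mediator product-of-coefficients model:
   condition → post-intervention amygdala–mPFC connectivity → bias, with
   pre-intervention connectivity (and optionally mood change and RMSSD
   change) as covariates in all three regressions, and percentile
   case-resampling bootstrap inference (`fit_model4()`). The Sobel test
   (`sobel()`) is kept as an analytic cross-check.
5. **Factorial ANOVAs.** Mixed-design ANOVAs with partial eta-squared
   cover the bias (2×2), the recognition measures (2×2×3) and the recall
   counts (2×2×3×2) (`fit_mixed_anova()`).

`run_pipeline()` executes 1–5 from CSV inputs and writes a results bundle
with a manifest of per-stage sample sizes and exclusions.

## The mediation model and its assumptions

With condition `x` (Osc+ = 0, Osc− = 1), mediator `m`, outcome `y`, and
covariate matrix `C`:

* `m = i1 + a·x + C·g1 + e1`
* `y = i2 + b·m + c′·x + C·g2 + e2`
* `y = i3 + c·x + C·g3 + e3`

The indirect effect is `ab`, and because all three OLS regressions share
the same sample and covariates, `c = c′ + a·b` holds to machine precision
— the package asserts this identity in its tests rather than trusting it.
Inference resamples whole participants with replacement, refits all three
regressions, and takes empirical quantiles of the replicate statistics.
The condition coding Osc+ = 0 / Osc− = 1 makes a bias *advantage* for the
Osc+ arm appear as negative `c` and `ab`, matching the sign conventions
used when such results are reported.

Numerical choices, fixed for reproducibility:

* quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7);
* percentile CIs, not bias-corrected ones — the default of the mediation
  macro this model reimplements; a BCa option is deliberately out of
  scope;
* bootstrap replicates in which the resampled condition vector is
  constant cannot identify the paths; they are redrawn and counted, with
  a warning past 10% redraws;
* `n_boot = 10000` by default (the conventional figure for this
  analysis); `n_boot = 0` is allowed for large simulation studies that
  need only point estimates.

## Krippendorff's alpha

Alpha is computed from the value-by-unit count matrix via the coincidence
matrix, `alpha = 1 − Do/De`. The metric is **nominal** by default even
though codes are 0/1/2, because the codes are match categories, not
magnitudes; an interval metric is exposed for sensitivity checks. Units
coded by fewer than two coders are excluded. A matrix whose coded entries
all carry one single value has `De = 0`; alpha is undefined there and the
package raises an error instead of returning 1 silently. The CI is a
nonparametric bootstrap over units (default 1000 replicates, percentile
method); degenerate replicates are skipped and counted. The procedure the
original coders used to resolve disagreements (discussion) cannot be
automated, so the merge rule is configurable and defaults to `max`
(favoring "reported"), which is also how the synthetic generator's truth
behaves.

## Mixed ANOVA

`fit_mixed_anova()` handles up to two between- and two within-subjects
factors. Each within-subject error stratum is isolated by projecting every
participant's response vector onto an orthonormal contrast basis (the
normalized constant column for factors averaged over, orthonormalized
Helmert contrasts for factors in the stratum); between-subjects effects
within a stratum then use Type III sums of squares from a sum-to-zero
coded full-factorial model, which is how the major commercial packages
treat unbalanced group sizes. Summed across the orthonormal columns these
SS reproduce the classical univariate partition exactly (the tests verify
this against a cell-means oracle and against `stats::aov` error strata on
balanced designs). No sphericity correction is applied, matching the
uncorrected integer degrees of freedom conventionally reported for these
designs; follow-up cell contrasts are likewise uncorrected. That is a
faithful-reproduction choice, not a statistical recommendation.

A constant dependent variable makes every stratum's error SS zero; the
table then reports `F = 0` (zero effect) with `p = NA` and a
`degenerate_error` attribute rather than `0/0`.

## The synthetic cohort generator

`generate_cohort()` draws complete trial datasets with known ground truth
so every downstream stage is testable without human data. Structure:

* condition `x ∈ {0, 1}` (Osc+ = 0), two age groups, `n_per_cell`
  participants per cell;
* pre-connectivity `~ N(0, 1)`;
  `post = rho_pre·pre + true_a·x + N(0, sigma_m)`;
* latent bias `= true_c_prime·x + true_b·post + N(0, sigma_y)`;
* the latent shifts valence-specific behavior: logit-scale shifts of
  `±bias_gain·latent` for hit and false-alarm probabilities (positive
  valence up, negative down), log-scale shifts for expected recall
  counts; recognition responses are item-level Bernoulli draws over 12
  items per valence × status cell, recall counts Poisson truncated at 12;
* coder 2 changes each item code with probability `coder_disagreement`;
  recalled-twice codes (2) occur with fixed probability 0.01; unmatched
  ("incorrect") recalls fill sentinel items so coder index sets stay
  identical.

**Default parameters are the study conditions the package emulates**, set
once: `n_per_cell = 40` (the trial's cells held 31–55); `base_hit = 0.86`
and `base_fa = 0.055` (observed recognition means); recall rates 4.0
(week 4) and 1.75 (week 5) per valence; `true_a = −0.35`,
`true_b = 0.45`, `true_c_prime = −0.28`, echoing the reported path
magnitudes (`ab ≈ −0.16`, `c ≈ −0.44` under the Osc− = 1 coding);
`coder_disagreement = 0.04`, which puts simulated reliability near the
reported alpha ≈ 0.9; `rho_pre = 0.5` with `sigma_m = 0.85` so pre and
post betas both have approximately unit variance (the standardized-beta
convention for connectivity weights — the source study reports no
distributional information about its betas, so unit scale is a
convention, not an estimate); `sigma_y = 1`. Age effects default to zero
(`oa_offset = 0`) because observed age effects were inconsistent.

**Interpreting `bias_gain`.** On the behavioral route the fitted indirect
effect lives on the composite-score scale, so only its *sign* is
comparable with `true_a·true_b`. For calibration studies that need the
effect on a known scale, use the stored latent (`cohort$latent`) as the
outcome: the latent is linear in the mediator, and the slope-scale true
indirect effect is exactly `true_a·true_b`. The coverage and recovery
studies below do this.

**What the generator does not emulate:** dropout and attrition,
item-level difficulty/memorability differences, age differences in memory
level, non-normal connectivity distributions, and any dependence of mood
or RMSSD change on condition. Passing calibration tests therefore show
the *machinery* is correct and well-calibrated under a clean linear
truth; they do not certify the substantive conclusions of any particular
human dataset.

## Calibration studies and problem sizes

The test suite and the acceptance script run, at sizes chosen to balance
Monte Carlo error against desk-scale runtimes:

* **Coverage:** 200 replicate cohorts, `n_per_cell = 60`, 1000 bootstrap
  resamples; the 95% percentile CI for `ab` should cover `true_a·true_b`
  with empirical coverage in [0.90, 0.99] (percentile intervals are known
  to run slightly below nominal at moderate n).
* **Recovery:** 100 cohorts with `true_a = 0.5`, `true_b = 0.6`,
  `n_per_cell = 250`; the fitted `ab` should land within ±25% of 0.30 in
  at least 90% of replicates.
* **Sign recovery through the full behavioral pipeline:** 100 cohorts,
  `n_per_cell = 250`, strong truth (`|true_a·true_b| ≥ 0.3`): at least
  95% sign agreement.
* **Sobel/bootstrap concordance:** 200 cohorts (half strong-effect, half
  null) at `n_per_cell = 100`; significance verdicts from the Sobel test
  and the bootstrap CI should agree in at least 95%.

## Known limitations and open choices

* The z-scores of the bias composite are computed over the
  listwise-complete participant set (those with both recognition and
  final-week recall); computing them over each measure's own sample
  before intersecting would change third-decimal results. The package
  standardizes after intersecting, which keeps the composite exactly
  zero-mean over the analyzed sample.
* The sample standard deviation (n − 1) is used throughout; population-sd
  z-scores would rescale the composite but not change test statistics.
* The alpha CI method attached to published reliability figures is often
  unstated; the bootstrap percentile CI here is a reasonable default, and
  exact reproduction of any particular printed CI is best-effort.
* Recall-coding inputs arrive as a single long CSV with `coder_id` and
  `week` columns; adapters for other deposited layouts are intentionally
  out of scope.
* Multiple mediators, moderated mediation, standardized effect sizes,
  Greenhouse–Geisser correction, and causal sensitivity analysis are
  non-goals.
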