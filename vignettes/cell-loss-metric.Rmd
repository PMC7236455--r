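---
title: "The TK1 cell-loss metric: model, calibration and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The TK1 cell-loss metric: model, calibration and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellloss)
```

## The model

Cytotoxic chemotherapy disrupts proliferating tumour cells, and thymidine
kinase 1 (TK1) — a cell-cycle-dependent enzyme present in S-phase cells —
leaks into the blood when they die. The serum concentration sTK1 (ng/ml)
therefore rises with treatment-induced cell death, but it also scales
with how much proliferating tumour there is. The cell-loss metric removes
that bulk dependence:

$$M = \frac{\mathrm{sTK1}}{V}, \qquad \Delta M_t = M_t - M_0,$$

with $V$ the clinical tumour volume in cm³, approximated as a sphere from
the largest diameter ($V = \pi d^3/6$), and $M_0$ the baseline metric,
which reflects spontaneous cell loss plus background TK1 release from
normal tissue. $M$ is an estimate of the proportion of proliferating
tumour cells being disrupted, in units of ng·ml⁻¹·cm⁻³.

Three timepoints carry the analysis: baseline, immediately before the
second chemotherapy cycle (available for a subset), and 48 h after the
second cycle. Only two tumour-size measurements exist — baseline and
between cycles 2 and 3 — so both on-treatment metrics divide by the
inter-cycle volume. This is a deliberate design decision, not an
approximation we can avoid: there is no dedicated pre-cycle-2 volume.

The pipeline (`run_analysis()`) then:

1. stratifies patients into quartiles of the baseline metric;
2. tabulates pathologic outcome at surgery (pCR, pT1, pT2, pT3) against
   quartile and tests the 2×4 pCR table with the Freeman–Halton exact
   test, plus all pairwise quartile comparisons (both pCR/non-pCR 2×2 and
   the three-category outcome);
3. compares volume, sTK1 and the metric between responders and
   non-responders at each timepoint (Wilcoxon rank-sum);
4. screens baseline covariates against pCR with one-way ANOVA;
5. runs ROC analysis of the 48 h metric (baseline-subtracted by default)
   with Youden cut-off selection, repeated on the pre-cycle-2 subset;
6. estimates the association between the 48 h metric and residual tumour
   volume among non-responders (Spearman, plus a log–log OLS slope).

pCR means absence of invasive cancer in the breast (residual DCIS
allowed); nodal status is deliberately excluded from the response
definition. Every analysis is complete-case for the fields it needs,
which is why the pre-cycle-2 block runs on a subset.

Both the baseline-subtracted and the raw 48 h metric variants are always
computed: the two define the same quartile membership (quartiles are cut
on the baseline metric either way) and the reports label them
explicitly. The ROC block defaults to $\Delta M$; `use_raw_metric_for_roc
= TRUE` switches to $M$.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `volume_shrink_mean` | 0.42 | fraction | median inter-cycle/baseline volume ratio (a 58% decrease) |
| `volume_shrink_sdlog` | 0.25 | log units | spread of the shrink multiplier |
| `pre2_fraction` | 1/1.5 | fraction | pre-cycle-2 sTK1 relative to the 48 h value |
| `pre2_sdlog` | 0.2 | log units | noise on that fraction |
| `pre2_missing_frac` | 47/104 | fraction | patients lacking the pre-cycle-2 sample |
| `residual_slope` | −0.5 | — | log-residual-volume per log-ΔM (inverse relation) |
| `residual_intercept` | −0.75 | log cm³ | level of the residual-volume model |
| `residual_noise_sd` | 0.8 | log units | residual-volume scatter |
| `baseline_stk1_floor` | 0.05 | ng/ml | assay floor on sampled baseline sTK1 |
| `seed` | 20200518 | — | reference-fixture seed |

The first five defaults restate the cohort's reported behaviour (58%
volume decrease in both response groups; 48 h sTK1 about 50% above the
pre-cycle-2 value; 57 of 104 patients with a pre-cycle-2 sample). The
residual-volume parameters are the package's own choices: the slope sign
encodes the observed inverse relation, and the intercept/noise were set
once so that, at the typical non-responder ΔM, residual tumours straddle
the 2 cm pT1/pT2 boundary roughly as the reported pT1 vs pT2+pT3 split
(38 vs 42 of 80) suggests. The pT classes use standard diameter
thresholds (2 cm and 5 cm) under the sphere formula; the source cohort's
exact thresholds are not printed.

## What the generator emulates — and what it does not

`generate_cohort()` reproduces, per baseline-metric quartile: the
baseline metric and baseline volume (lognormals fitted to printed
median/Q1/Q3), the baseline-subtracted 48 h metric (shifted lognormals;
the shift of 0.02 in quartiles 1–2 admits the printed negative minima),
and the pCR probability (3/26, 3/26, 6/26, 12/26). Baseline sTK1 is
emergent (metric × volume, floored at the assay floor), as are its
summaries; they are not directly calibrated. Covariates (age, menopause,
stage, histology, subtype, ER/PR, Ki67, nodal status) are drawn from the
per-quartile marginal frequencies of the published baseline table and are
independent of outcome — the published covariate screen found no
significant associations, and the generator deliberately encodes none.

Known departures from real data:

* **Within-quartile independence.** Baseline metric and volume are drawn
  independently within quartile; the real joint distribution is unknown
  (across quartiles the printed medians show an inverse pattern, which
  the per-quartile calibration already captures).
* **Calibration law vs printed IQR.** The lognormal fit
  (`lognormal_from_median_iqr()`) matches the median exactly and the
  Q3/Q1 *ratio* exactly: $\mu = \ln(\text{median})$, $\sigma =
  \ln(Q3/Q1)/(2 z_{0.75})$. When a printed triple is not geometrically
  symmetric ($Q1 \cdot Q3 \ne \text{median}^2$) no lognormal with these
  parameters reproduces the printed IQR; for the quartile-4 48 h metric
  the fitted IQR is 0.414 against a printed 0.360. `fitted_quartiles()`
  exposes what the sampler converges to, and the calibration tests check
  medians against the configured values and IQRs against the fitted
  closed form.
* **No kinetics.** sTK1 is modelled per timepoint, not as a time course;
  missingness is a Bernoulli fraction, not a mechanism; there is no
  nodal TK1 release and no dropout.

Consequently, passing tests demonstrate that the pipeline recovers the
structure the generator encodes (quartile separation, outcome gradients,
the inverse residual-volume relation) — they cannot certify behaviour on
features the generator omits, such as covariate–outcome confounding or
assay drift.

## Numerical conventions

* **Quantiles.** Linear interpolation at position $(n-1)p$ between order
  statistics (R type 7), centralized in `summary_stats()` and switchable
  via its `type` argument. The original analyses were run in SAS, whose
  default percentile definition differs; with no patient-level data, no
  printed quantile can adjudicate, so one common convention is used and
  exposed.
* **Quartile assignment** is by rank blocks (stable ties by patient id,
  larger blocks first), guaranteeing group sizes that differ by at most
  one — exactly 26/26/26/26 at n = 104 — regardless of ties. Boundaries
  are reported as midpoints between straddling values.
* **Fisher/Freeman–Halton.** Two-sided p by the probability-mass
  criterion: total probability of tables (under the multivariate
  hypergeometric null with fixed margins) no more likely than the
  observed one, compared with relative tolerance 1e−12. The table space
  is enumerated depth-first with a configurable cap (default 10⁷ tables;
  exceeding it is an error, never a silent approximation). A zero margin
  returns p = 1, flagged degenerate.
* **Wilcoxon.** Exact enumeration for the signed-rank test when the
  effective n ≤ 12 (all 2ⁿ sign vectors) and for the rank-sum test when
  min(n, m) ≤ 10 *and* the subset space is ≤ 2·10⁵ (the extra guard
  prevents pathological cases such as 10 vs 1000); otherwise the normal
  approximation with tie and continuity correction. Exact two-sided
  p-values are 2·min(tails), capped at 1. Zero differences are dropped;
  all-zero differences give p = 1, degenerate.
* **ANOVA degeneracy.** Zero within-group variance yields p = 0 with
  unequal means and p = 1 with equal means, both flagged.
* **ROC.** Higher metric ⇒ predicted pCR; test-positive iff score ≥
  cutoff (the inclusive rule lets a printed cut-off coincide with an
  observed value). The trapezoidal AUC over the threshold sweep equals
  the tie-corrected rank statistic (ties count ½). Youden's J breaks
  ties toward higher specificity, then the higher cutoff; cutoffs are
  reported as midpoints between adjacent distinct scores.
* **Rounding.** Printed-precision comparisons use half-up rounding
  (`round_half_up()`), since half-even cannot reproduce printed rates
  like 40.5% from 24.8 → 25. Reports round percentages to 1 decimal,
  metrics to 4, p-values to 3 (2 when ≥ 0.01), always retaining the
  full-precision values alongside.
* **Residual-volume association.** The method behind the published
  inverse relation is unstated; the default is Spearman correlation of
  ΔM with residual volume among non-responders, with a log–log OLS slope
  reported alongside for transparency. The pre-cycle-2 predictive block
  needs a cut-off the source does not print; the Youden optimum on that
  subset is used and labelled a reconstruction.

## Problem sizes in the test suite

Calibration checks use 10⁴–10⁵ draws per quartile variable; the
structural AUC check averages 500 cohorts of n = 104; the null
(type-I-error) check uses 300 cohorts under an outcome-independent
generator, with an a-priori acceptance band of [0.01, 0.075] around the
nominal 5% to accommodate the exact test's conservatism on discrete 2×4
tables. These sizes keep Monte-Carlo error well inside the asserted
tolerances.

## Limitations

The package analyses a single-cohort design: no cross-validation, no
confidence interval on the AUC, no multiple-testing correction (matching
the original analysis plan), and no modelling of TK1 kinetics or nodal
release. The synthetic cohort is a calibrated stand-in, suitable for
validating code paths and structural behaviour, not for estimating
clinical operating characteristics.
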