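# cellloss

Early prediction of pathologic complete response (pCR) to neoadjuvant
chemotherapy in breast cancer, using a serum-biomarker **cell-loss
metric**. Dying proliferating cells release thymidine kinase 1 into the
blood; relating its serum concentration to tumour bulk yields a per-volume
measure of treatment-induced tumour-cell disruption:

```
M = sTK1 / V        [ng·ml⁻¹·cm⁻³]
ΔM_t = M_t − M_0
```

where `sTK1` is the serum TK1 concentration (ng/ml), `V` the clinical
tumour volume (cm³, sphere approximation `V = πd³/6` from the largest
diameter), `M_0` the pre-treatment (baseline) metric and `M_t` the metric
before or 48 h after the second chemotherapy cycle, divided by the
tumour volume measured between cycles 2 and 3. Baseline subtraction
isolates treatment-induced cell loss from spontaneous turnover.

The package is aimed at biostatisticians and translational oncology
groups evaluating early on-treatment biomarkers. It provides:

* a validated patient-level cohort format (CSV, wide over timepoints)
  with read/write/validation tools;
* metric computation at the three timepoints (`compute_metrics()`);
* quartile stratification on the baseline metric by rank blocks
  (`assign_quartiles()`) and descriptive tables (`group_summaries()`);
* hand-implemented exact inference: the Freeman–Halton (Fisher) exact
  test on 2×k outcome tables by full enumeration (`fisher_exact_2xk()`),
  Wilcoxon signed-rank/rank-sum with exact small-sample enumeration,
  one-way ANOVA, Spearman correlation;
* ROC analysis with Youden cut-off selection (`roc_curve()`,
  `youden_cutoff()`), and audit tools that reconstruct integer confusion
  matrices from rounded printed rates (`reconstruct_confusion()`,
  `enumerate_consistent_matrices()`);
* a calibrated synthetic-cohort generator (`generate_cohort()`), since
  the underlying clinical-trial patient data are not publicly deposited;
* a one-call pipeline (`run_analysis()`) and a small CLI
  (`inst/cli/cellloss`: `simulate`, `analyze`, `roc`, `reconstruct`).

## Worked example

```r
library(cellloss)

co  <- generate_cohort(generator_config(seed = 20200518))
co
#> <cohort> 104 patients (provenance: synthetic, seed 20200518)
#>   pre-cycle-2 sTK1 available: 58; pCR: 24

rep <- run_analysis(co)
rep
#> <cellloss_report> 104 patients
#>   pCR by quartile: 2/6/6/10 (7.7/23.1/23.1/38.5%)
#>   Fisher 2x4 p = 0.071
#>   ROC (dm_post2): AUC = 0.653, Youden cutoff = 0.01487 (sens 0.79, spec 0.53)
#>   pre-cycle-2 subset (n = 58): AUC = 0.605, PPV 42.1%, NPV 82.1%
#>   residual volume vs dm_post2 (non-pCR): Spearman rho = -0.730, p = 1.606e-14
```

One synthetic cohort of 104 patients is drawn (26 per baseline-metric
quartile); 24 reach pCR. The report shows the pCR count and percentage
per quartile, the exact 2×4 test of whether the pCR distribution differs
across quartiles, the ROC of the baseline-subtracted 48 h metric with its
Youden-optimal cut-off, the same predictive block on the pre-cycle-2
subset, and the inverse association between the 48 h metric and residual
tumour volume among non-responders. Individual cohorts fluctuate; the
acceptance script below averages over many.

Auditing printed predictive values from their margins and rounded rates:

```r
reconstruct_confusion(n_pos = 24, n_neg = 80,
                      sensitivity = 0.71, one_minus_specificity = 0.31)
#> tp 17 fp 25 fn 7 tn 55
#>   sens 0.708  spec 0.688  PPV 40.5%  NPV 88.7%
```

## Documentation

The methods vignette (`vignettes/cell-loss-metric.Rmd`) describes the
model, the calibration of the synthetic generator and its limitations,
and the numerical conventions (quantile definition, exact-test
enumeration, tie handling, rounding).
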