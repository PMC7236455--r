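#' Run the full cell-loss analysis on a cohort
#'
#' Executes the whole pipeline deterministically: per-patient metrics,
#' quartile assignment on the baseline metric, descriptive group tables
#' for both the baseline-subtracted and the raw 48 h metric (the two
#' variants share the same quartile membership by construction), the
#' pathologic-outcome-by-quartile contingency analysis (Freeman-Halton
#' 2 x 4 plus all pairwise quartile comparisons, both as pCR/non-pCR 2 x 2
#' and over the three-category outcome), pCR vs non-pCR Wilcoxon
#' comparisons of tumour volume, sTK1 and the metric at the three
#' timepoints, one-way ANOVAs of pCR against the baseline covariates,
#' ROC analysis of the 48 h metric with Youden cut-off selection (and the
#' same block on the pre-cycle-2 subset), and the Spearman correlation of
#' the 48 h metric with residual tumour volume among non-responders
#' (with a log-log OLS slope reported alongside).
#'
#' @param cohort a validated [cohort_table()] with >= 8 records.
#' @param use_raw_metric_for_roc if TRUE, the ROC block scores patients by
#'   the raw 48 h metric instead of the baseline-subtracted one.
#' @return list of class `cellloss_report`.
#' @export
run_analysis <- function(cohort, use_raw_metric_for_roc = FALSE) {
  if (nrow(cohort) < 8) {
    stop_cellloss("run_analysis requires >= 8 records", "cellloss_precondition_error")
  }
  f <- validate_cohort(cohort)
  if (any(f$severity == "error")) {
    stop_cellloss(paste0("stage validate: cohort has ", sum(f$severity == "error"),
                         " error finding(s)"), "cellloss_validation_error")
  }
  metrics <- compute_metrics(cohort)
  grouping <- assign_quartiles(
    stats::setNames(metrics$m_baseline, metrics$patient_id),
    stratifier = "baseline cell-loss metric")
  joined <- merge(as.data.frame(cohort), metrics, by = "patient_id", sort = FALSE)
  # merge preserves nothing reliably; restore the cohort's row order
  joined <- joined[match(cohort$patient_id, joined$patient_id), ]
  grp <- grouping$labels[joined$patient_id]

  descriptive <- list(
    baseline = group_summaries(joined, grouping,
                               c("age", "vol_baseline_cm3", "stk1_baseline",
                                 "m_baseline", "menopause", "histology", "subtype",
                                 "er_positive", "pr_positive", "ki67_percent",
                                 "node_positive")),
    dm_post2 = group_summaries(joined, grouping, "dm_post2"),
    m_post2 = group_summaries(joined, grouping, "m_post2"))

  pcr <- joined$outcome == "pCR"
  counts_pcr <- vapply(1:4, function(q) sum(pcr & grp == q), integer(1))
  sizes <- vapply(1:4, function(q) sum(grp == q), integer(1))
  outcome3 <- ifelse(joined$outcome == "pCR", "pCR",
                     ifelse(joined$outcome == "pT1", "pT1", "pT2+pT3"))
  tab_2x4 <- contingency_table(rbind(pCR = counts_pcr, non_pCR = sizes - counts_pcr),
                               col_labels = paste0("Q", 1:4))
  outcome_by_quartile <- list(
    table = tab_2x4,
    pcr_percent = 100 * counts_pcr / sizes,
    outcome3 = table(outcome3, factor(grp, levels = 1:4)))

  tests <- list(fisher_2x4 = fisher_exact_2xk(tab_2x4))
  for (pair in utils::combn(4, 2, simplify = FALSE)) {
    i <- pair[1]; j <- pair[2]
    nm <- sprintf("fisher_q%d_vs_q%d", i, j)
    tests[[nm]] <- fisher_exact_2xk(tab_2x4[, c(i, j)])
    sub <- grp %in% c(i, j)
    t3 <- table(factor(outcome3[sub], levels = c("pCR", "pT1", "pT2+pT3")),
                factor(grp[sub], levels = c(i, j)))
    tests[[sprintf("fisher3_q%d_vs_q%d", i, j)]] <- fisher_exact_2xk(t(as.matrix(t3)))
  }

  # pCR vs non-pCR at the three timepoints (volume, sTK1, metric)
  cmp_vars <- list(
    baseline_volume = joined$vol_baseline,
    baseline_stk1 = joined$stk1_baseline,
    baseline_metric = joined$m_baseline,
    pre_cycle2_stk1 = joined$stk1_pre_cycle2,
    pre_cycle2_metric = joined$m_pre2,
    pre_cycle2_dm = joined$dm_pre2,
    post_cycle2_volume = joined$vol_intercycle,
    post_cycle2_stk1 = joined$stk1_post_cycle2_48h,
    post_cycle2_metric = joined$m_post2,
    post_cycle2_dm = joined$dm_post2)
  response_comparison <- lapply(cmp_vars, function(v) {
    keep <- !is.na(v)
    if (sum(keep & pcr) == 0 || sum(keep & !pcr) == 0) return(NULL)
    r <- wilcoxon_test(v[keep & pcr], v[keep & !pcr])
    list(test = r,
         pcr = summary_stats(v[keep & pcr]),
         non_pcr = summary_stats(v[keep & !pcr]))
  })

  covariates <- list(
    stage = as.character(joined$stage), menopause = joined$menopause,
    er_positive = joined$er_positive, pr_positive = joined$pr_positive,
    histology = joined$histology, node_positive = joined$node_positive,
    subtype = joined$subtype, ki67_percent = joined$ki67_percent)
  anova_tests <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    keep <- !is.na(v)
    if (is.numeric(v)) {
      # numeric covariate: compare its values between responders and not
      groups <- split(v[keep], pcr[keep])
    } else {
      groups <- split(as.numeric(pcr[keep]), v[keep])
      groups <- groups[lengths(groups) > 0]
    }
    if (length(groups) < 2) return(NULL)
    anova_oneway(groups)
  })
  names(anova_tests) <- names(covariates)

  roc_scores <- if (use_raw_metric_for_roc) joined$m_post2 else joined$dm_post2
  roc_main <- roc_curve(stats::setNames(roc_scores, joined$patient_id), pcr)
  youden_main <- youden_cutoff(stats::setNames(roc_scores, joined$patient_id), pcr)
  # Mann-Whitney p for the AUC (same ranks as the rank-sum test)
  auc_p <- wilcoxon_test(roc_scores[pcr], roc_scores[!pcr])

  has57 <- !is.na(joined$dm_pre2)
  subset_n57 <- NULL
  if (sum(has57 & pcr) >= 1 && sum(has57 & !pcr) >= 1) {
    s57 <- stats::setNames(joined$dm_pre2[has57], joined$patient_id[has57])
    l57 <- pcr[has57]
    y57 <- youden_cutoff(s57, l57)
    subset_n57 <- list(n = sum(has57), roc = roc_curve(s57, l57),
                       youden = y57, confusion = y57$confusion)
  }

  nonpcr <- !pcr & joined$residual_volume_cm3 > 0
  residual <- NULL
  if (sum(nonpcr) >= 3) {
    dmv <- joined$dm_post2[nonpcr]
    rv <- joined$residual_volume_cm3[nonpcr]
    fit <- stats::lm(log(rv) ~ log(pmax(dmv, 1e-6)))
    residual <- list(spearman = spearman_correlation(dmv, rv),
                     log_ols_slope = unname(stats::coef(fit)[2]))
  }

  structure(list(n = nrow(cohort),
                 grouping = grouping,
                 metrics = metrics,
                 descriptive = descriptive,
                 outcome_by_quartile = outcome_by_quartile,
                 tests = tests,
                 response_comparison = response_comparison,
                 anova = anova_tests,
                 roc = list(curve = roc_main, youden = youden_main,
                            confusion = youden_main$confusion, auc_p = auc_p,
                            score = if (use_raw_metric_for_roc) "m_post2" else "dm_post2"),
                 subset_n57 = subset_n57,
                 residual = residual),
            class = "cellloss_report")
}

#' @export
print.cellloss_report <- function(x, ...) {
  cat(sprintf("<cellloss_report> %d patients\n", x$n))
  cat(sprintf("  pCR by quartile: %s (%s%%)\n",
              paste(x$outcome_by_quartile$table[1, ], collapse = "/"),
              paste(round_half_up(x$outcome_by_quartile$pcr_percent, 1), collapse = "/")))
  cat(sprintf("  Fisher 2x4 p = %.3f\n", x$tests$fisher_2x4$p_value))
  cat(sprintf("  ROC (%s): AUC = %.3f, Youden cutoff = %.4g (sens %.2f, spec %.2f)\n",
              x$roc$score, x$roc$curve$auc, x$roc$youden$cutoff,
              x$roc$confusion$sensitivity, x$roc$confusion$specificity))
  if (!is.null(x$subset_n57)) {
    cat(sprintf("  pre-cycle-2 subset (n = %d): AUC = %.3f, PPV %.1f%%, NPV %.1f%%\n",
                x$subset_n57$n, x$subset_n57$roc$auc,
                100 * x$subset_n57$confusion$ppv, 100 * x$subset_n57$confusion$npv))
  }
  if (!is.null(x$residual)) {
    cat(sprintf("  residual volume vs dm_post2 (non-pCR): Spearman rho = %.3f, p = %.4g\n",
                x$residual$spearman$statistic, x$residual$spearman$p_value))
  }
  invisible(x)
}

.round_report <- function(x) {
  # reporting-layer rounding: percentages 1 dp, metrics 4 dp, p-values 3 dp
  # (2 dp when >= 0.01); raw values always kept alongside
  pround <- function(p) if (is.na(p)) NA_real_ else if (p >= 0.01) round_half_up(p, 2) else round_half_up(p, 3)
  list(pcr_percent = round_half_up(x$outcome_by_quartile$pcr_percent, 1),
       fisher_2x4_p = pround(x$tests$fisher_2x4$p_value),
       auc = round_half_up(x$roc$curve$auc, 3),
       cutoff = round_half_up(x$roc$youden$cutoff, 4))
}

#' Serialize an analysis report to JSON
#'
#' @param report a `cellloss_report`.
#' @param path output file, or NULL to return the JSON string.
#' @return invisibly the path, or the JSON string when `path` is NULL.
#' @export
report_json <- function(report, path = NULL) {
  tr <- function(t) if (is.null(t)) NULL else unclass(t)
  body <- list(
    n = report$n,
    quartile_sizes = report$grouping$sizes,
    quartile_boundaries = report$grouping$boundaries,
    outcome_by_quartile = list(
      pcr = as.integer(report$outcome_by_quartile$table[1, ]),
      non_pcr = as.integer(report$outcome_by_quartile$table[2, ]),
      pcr_percent = report$outcome_by_quartile$pcr_percent),
    tests = lapply(report$tests, tr),
    anova = lapply(report$anova, tr),
    response_comparison = lapply(report$response_comparison, function(b) {
      if (is.null(b)) return(NULL)
      list(test = tr(b$test), pcr = unclass(b$pcr), non_pcr = unclass(b$non_pcr))
    }),
    roc = list(score = report$roc$score, auc = report$roc$curve$auc,
               auc_p = tr(report$roc$auc_p),
               cutoff = report$roc$youden$cutoff,
               confusion = unclass(report$roc$confusion)),
    subset_n57 = if (is.null(report$subset_n57)) NULL else
      list(n = report$subset_n57$n, auc = report$subset_n57$roc$auc,
           cutoff = report$subset_n57$youden$cutoff,
           confusion = unclass(report$subset_n57$confusion)),
    residual = if (is.null(report$residual)) NULL else
      list(spearman = tr(report$residual$spearman),
           log_ols_slope = report$residual$log_ols_slope),
    rounded = .round_report(report))
  js <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Export ROC points as CSV
#'
#' @param roc a `roc_curve`.
#' @param path output CSV (threshold, fpr, tpr).
#' @return invisibly the path.
#' @export
roc_csv <- function(roc, path) {
  utils::write.csv(roc$points, path, row.names = FALSE)
  invisible(path)
}
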