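# Builders for small hand-made fixtures used across test files.

# n-patient cohort with fully specified, easily hand-checked numbers.
make_tiny_cohort <- function(n = 8) {
  stopifnot(n >= 2)
  ids <- sprintf("P%02d", seq_len(n))
  # baseline metric increases with index: stk1 fixed 0.4, volume decreasing
  vol_b <- seq(400, 50, length.out = n)
  vol_ic <- vol_b * 0.5
  stk1_b <- rep(0.4, n)
  stk1_48 <- seq(0.5, 2.0, length.out = n)
  outcome <- rep(c("pT2", "pT1"), length.out = n)
  outcome[n] <- "pCR"
  res <- ifelse(outcome == "pCR", 0, ifelse(outcome == "pT1", 2, 30))
  cohort_table(data.frame(
    patient_id = ids,
    stk1_baseline = stk1_b,
    stk1_pre_cycle2 = c(rep(NA_real_, floor(n / 2)), stk1_48[(floor(n / 2) + 1):n] / 1.5),
    stk1_post_cycle2_48h = stk1_48,
    vol_baseline_cm3 = vol_b,
    vol_intercycle_cm3 = vol_ic,
    outcome = outcome,
    residual_volume_cm3 = res,
    age = seq(40, 60, length.out = n),
    menopause = rep(c("pre", "post"), length.out = n),
    stage = rep(2L, n),
    histology = rep("ductal", n),
    subtype = rep(c("lumA", "lumB"), length.out = n),
    er_positive = rep(TRUE, n),
    pr_positive = rep(c(TRUE, FALSE), length.out = n),
    ki67_percent = rep(30, n),
    node_positive = rep(FALSE, n),
    stringsAsFactors = FALSE), provenance = "hand-built fixture")
}

# Profiles whose baseline-metric supports cannot overlap between quartiles
# (degenerate point distributions), forcing perfect quartile recovery.
disjoint_profiles <- function() {
  mk <- function(m, pcr) quartile_profile(
    baseline_metric = c(m, m, m),
    baseline_volume = c(100, 100, 100),
    dm_post2 = c(10 * m, 10 * m, 10 * m),
    dm_shift = 0, pcr_prob = pcr)
  list(mk(0.001, 3 / 26), mk(0.01, 3 / 26), mk(0.1, 6 / 26), mk(1, 12 / 26))
}

# Null generator: metric structure as default but pCR probability equal in
# every quartile (no metric/outcome association).
null_config <- function(seed, n = 104) {
  prof <- lapply(default_profiles(), function(p) {
    p$pcr_prob <- 24 / 104
    p
  })
  generator_config(n = n, profiles = prof, seed = seed)
}
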