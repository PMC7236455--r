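#' Spherical tumour volume from its largest diameter
#'
#' Tumours are treated as spheres; the volume is pi * d^3 / 6 for largest
#' diameter d in cm.
#'
#' @param largest_diameter_cm diameter(s) in cm, strictly positive.
#' @return volume(s) in cm3.
#' @export
#' @examples
#' sphere_volume(2)   # 4.19 cm3
sphere_volume <- function(largest_diameter_cm) {
  if (any(!is.finite(largest_diameter_cm)) || any(largest_diameter_cm <= 0)) {
    stop_cellloss("diameter must be finite and > 0", "cellloss_domain_error")
  }
  pi * largest_diameter_cm^3 / 6
}

#' Largest diameter from a spherical volume (inverse of sphere_volume)
#' @param volume_cm3 volume(s) in cm3, >= 0.
#' @return diameter(s) in cm.
#' @export
sphere_diameter <- function(volume_cm3) {
  if (any(!is.finite(volume_cm3)) || any(volume_cm3 < 0)) {
    stop_cellloss("volume must be finite and >= 0", "cellloss_domain_error")
  }
  (6 * volume_cm3 / pi)^(1 / 3)
}

#' The cell-loss metric: sTK1 per unit tumour volume
#'
#' The ratio between the serum concentration of thymidine kinase 1
#' (ng/ml) and the clinical tumour volume (cm3). It estimates the
#' proportion of proliferating tumour cells being disrupted: TK1 is
#' released into blood when proliferating cells die, and dividing by
#' volume removes the trivial dependence of sTK1 on tumour bulk.
#' Units: ng ml^-1 cm^-3.
#'
#' @param stk1 serum TK1 concentration(s), ng/ml, >= 0.
#' @param volume tumour volume(s), cm3, strictly > 0 (a measured volume of
#'   0 is rejected, never turned into an infinite metric).
#' @return metric value(s).
#' @export
cell_loss_metric <- function(stk1, volume) {
  if (any(!is.finite(stk1)) || any(stk1 < 0)) {
    stop_cellloss("stk1 must be finite and >= 0", "cellloss_domain_error")
  }
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop_cellloss("volume must be finite and > 0", "cellloss_domain_error")
  }
  stk1 / volume
}

#' Baseline subtraction of the cell-loss metric
#'
#' Subtracts the pre-treatment metric from an on-treatment metric to
#' isolate treatment-induced cell loss; negative values are legal and
#' preserved (the on-treatment metric can fall below baseline).
#'
#' @param m_t on-treatment metric value(s).
#' @param m_0 baseline metric value(s).
#' @return m_t - m_0.
#' @export
baseline_subtract <- function(m_t, m_0) {
  if (any(!is.finite(m_t)) || any(!is.finite(m_0))) {
    stop_cellloss("metric values must be finite", "cellloss_domain_error")
  }
  m_t - m_0
}

.resolve_volume <- function(vol, diam) {
  out <- vol
  use_d <- is.na(out) & !is.na(diam)
  out[use_d] <- sphere_volume(diam[use_d])
  out
}

#' Compute per-patient cell-loss metrics
#'
#' For each patient: the baseline metric (baseline sTK1 / baseline volume),
#' the 48 h post-cycle-2 metric (48 h sTK1 / inter-cycle volume), the
#' pre-cycle-2 metric when that sample exists (pre-cycle-2 sTK1 /
#' inter-cycle volume — only two volume measurements exist, so the
#' inter-cycle volume serves both on-treatment timepoints), and the
#' baseline-subtracted versions of the two on-treatment metrics.
#'
#' Volumes are taken from the volume columns when present and otherwise
#' derived from the largest diameter via [sphere_volume()].
#'
#' @param cohort a [cohort_table()] (or a single-row subset).
#' @return data.frame with one row per patient: patient_id, vol_baseline,
#'   vol_intercycle, m_baseline, m_pre2, m_post2, dm_pre2, dm_post2.
#'   m_pre2/dm_pre2 are NA when the pre-cycle-2 sample is absent.
#' @export
compute_metrics <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  vol_b <- .resolve_volume(cohort$vol_baseline_cm3, cohort$diam_baseline_cm)
  vol_ic <- .resolve_volume(cohort$vol_intercycle_cm3, cohort$diam_intercycle_cm)
  .require_field <- function(x, field) {
    if (any(is.na(x))) {
      id <- cohort$patient_id[which(is.na(x))[1]]
      stop_cellloss(paste0("patient ", id, ": missing required field ", field),
                    "cellloss_precondition_error")
    }
  }
  .require_field(cohort$stk1_baseline, "stk1_baseline")
  .require_field(vol_b, "baseline volume (vol_baseline_cm3 or diam_baseline_cm)")
  .require_field(cohort$stk1_post_cycle2_48h, "stk1_post_cycle2_48h")
  .require_field(vol_ic, "inter-cycle volume (vol_intercycle_cm3 or diam_intercycle_cm)")

  m_baseline <- cell_loss_metric(cohort$stk1_baseline, vol_b)
  m_post2 <- cell_loss_metric(cohort$stk1_post_cycle2_48h, vol_ic)
  has_pre2 <- !is.na(cohort$stk1_pre_cycle2)
  m_pre2 <- rep(NA_real_, nrow(cohort))
  m_pre2[has_pre2] <- cell_loss_metric(cohort$stk1_pre_cycle2[has_pre2], vol_ic[has_pre2])
  dm_post2 <- baseline_subtract(m_post2, m_baseline)
  dm_pre2 <- rep(NA_real_, nrow(cohort))
  dm_pre2[has_pre2] <- baseline_subtract(m_pre2[has_pre2], m_baseline[has_pre2])

  data.frame(patient_id = cohort$patient_id,
             vol_baseline = vol_b, vol_intercycle = vol_ic,
             m_baseline = m_baseline, m_pre2 = m_pre2, m_post2 = m_post2,
             dm_pre2 = dm_pre2, dm_post2 = dm_post2,
             stringsAsFactors = FALSE)
}
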