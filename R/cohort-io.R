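#' @title Cohort table: the patient-level data model
#'
#' @description
#' One row per patient, wide over timepoints. Serum thymidine kinase 1
#' (sTK1, ng/ml) is recorded at baseline, before cycle 2 (optional) and
#' 48 h after cycle 2; tumour size at baseline and between cycles 2 and 3,
#' as the largest diameter (cm) and/or the derived spherical volume (cm3).
#' Pathologic outcome at surgery is one of pCR, pT1, pT2, pT3, with the
#' residual tumour volume (0 exactly when pCR). Baseline covariates follow
#' the usual breast-cancer work-up (age, menopause, stage, histology,
#' intrinsic subtype, ER/PR status, Ki67 labelling index, nodal status).
#'
#' @details
#' The CSV dialect is fixed: comma-separated, UTF-8, '.' decimal separator,
#' mandatory header, missing values as empty fields. Units are fixed at
#' ng/ml, cm and cm3; there is no unit auto-detection.
#'
#' @name cohort
NULL

#' Ordered timepoint labels
#' @export
timepoint_keys <- function() c("baseline", "pre_cycle2", "post_cycle2_48h", "surgery")

#' Canonical cohort CSV column order
#' @export
cohort_columns <- function() c(
  "patient_id",
  "stk1_baseline", "stk1_pre_cycle2", "stk1_post_cycle2_48h",
  "diam_baseline_cm", "diam_intercycle_cm",
  "vol_baseline_cm3", "vol_intercycle_cm3",
  "outcome", "residual_volume_cm3",
  "age", "menopause", "stage", "histology", "subtype",
  "er_positive", "pr_positive", "ki67_percent", "node_positive"
)

.outcome_levels <- c("pCR", "pT1", "pT2", "pT3")
.required_columns <- c("patient_id", "stk1_baseline", "stk1_post_cycle2_48h",
                       "outcome", "residual_volume_cm3")
.numeric_columns <- c("stk1_baseline", "stk1_pre_cycle2", "stk1_post_cycle2_48h",
                      "diam_baseline_cm", "diam_intercycle_cm",
                      "vol_baseline_cm3", "vol_intercycle_cm3",
                      "residual_volume_cm3", "age", "ki67_percent")
.logical_columns <- c("er_positive", "pr_positive", "node_positive")

#' Construct a cohort table
#'
#' @param records data.frame with (a subset of) [cohort_columns()];
#'   missing optional columns are added as NA.
#' @param provenance free-text source tag.
#' @param seed integer seed used to generate the cohort, or NULL.
#' @param validate if TRUE (default), error on validation findings of
#'   severity "error".
#' @return an object of class `cohort` (a data.frame).
#' @export
cohort_table <- function(records, provenance = "unspecified", seed = NULL,
                         validate = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_req <- setdiff(.required_columns, names(records))
  if (length(missing_req) > 0) {
    stop_cellloss(paste0("missing required column(s): ",
                         paste(missing_req, collapse = ", ")),
                  "cellloss_schema_error")
  }
  if (!any(c("vol_baseline_cm3", "diam_baseline_cm") %in% names(records))) {
    stop_cellloss("missing required column(s): vol_baseline_cm3 or diam_baseline_cm",
                  "cellloss_schema_error")
  }
  for (col in setdiff(cohort_columns(), names(records))) {
    fill <- if (col %in% .numeric_columns) NA_real_
      else if (col %in% .logical_columns) NA
      else NA_character_
    records[[col]] <- rep(fill, nrow(records))
  }
  records <- records[, cohort_columns(), drop = FALSE]
  records$patient_id <- as.character(records$patient_id)
  for (col in .numeric_columns) records[[col]] <- as.numeric(records[[col]])
  for (col in .logical_columns) records[[col]] <- as.logical(records[[col]])
  records$stage <- as.integer(records$stage)
  rownames(records) <- NULL
  out <- structure(records,
                   provenance = provenance,
                   seed = seed,
                   class = c("cohort", "data.frame"))
  if (nrow(out) > 0 && anyDuplicated(out$patient_id)) {
    dup <- out$patient_id[duplicated(out$patient_id)][1]
    stop_cellloss(paste0("duplicate patient_id: ", dup), "cellloss_validation_error")
  }
  if (validate && nrow(out) > 0) {
    f <- validate_cohort(out)
    bad <- f[f$severity == "error", , drop = FALSE]
    if (nrow(bad) > 0) {
      stop_cellloss(paste0("cohort validation failed: ", bad$patient_id[1], " / ",
                           bad$field[1], ": ", bad$message[1],
                           if (nrow(bad) > 1) paste0(" (and ", nrow(bad) - 1, " more)") else ""),
                    "cellloss_validation_error")
    }
  }
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients (provenance: %s%s)\n", nrow(x),
              attr(x, "provenance") %||% "unspecified",
              if (!is.null(attr(x, "seed"))) paste0(", seed ", attr(x, "seed")) else ""))
  n57 <- sum(!is.na(x$stk1_pre_cycle2))
  cat(sprintf("  pre-cycle-2 sTK1 available: %d; pCR: %d\n",
              n57, sum(x$outcome == "pCR", na.rm = TRUE)))
  invisible(x)
}

#' Read a cohort CSV
#'
#' @param path path to a CSV in the documented wide format.
#' @param strict if TRUE (default), stop on validation findings of severity
#'   "error"; if FALSE, return the cohort and leave findings to
#'   [validate_cohort()].
#' @return a [cohort_table()] with row order preserved.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_cellloss(paste0("file not found: ", path), "cellloss_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         na.strings = "")
  missing_req <- setdiff(c(.required_columns, "vol_baseline_cm3"), names(raw))
  # diameter may stand in for volume
  if ("vol_baseline_cm3" %in% missing_req && "diam_baseline_cm" %in% names(raw)) {
    missing_req <- setdiff(missing_req, "vol_baseline_cm3")
  }
  if (length(missing_req) > 0) {
    stop_cellloss(paste0("cohort CSV lacks required column(s): ",
                         paste(missing_req, collapse = ", ")),
                  "cellloss_schema_error")
  }
  cohort_table(raw, provenance = paste0("file:", path), validate = strict)
}

#' Write a cohort CSV
#'
#' Numbers are written with shortest round-trip precision; missing values
#' become empty fields; columns follow [cohort_columns()].
#'
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- as.data.frame(cohort)
  for (col in names(df)) {
    v <- df[[col]]
    df[[col]] <- ifelse(is.na(v), "", as.character(v))
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_cellloss(paste0("cannot write: ", path), "cellloss_io_error")
  invisible(path)
}

.finding <- function(patient_id, field, message, severity = "error") {
  data.frame(patient_id = patient_id, field = field, message = message,
             severity = severity, stringsAsFactors = FALSE)
}

#' Validate a cohort
#'
#' Checks the record-level invariants and returns findings rather than
#' raising: negative concentrations/volumes, outcome/residual-volume
#' inconsistency (pCR if and only if residual volume 0), missing baseline
#' measurements, and diameter/volume pairs inconsistent by more than 1%
#' under the sphere formula (warning severity).
#'
#' @param cohort a [cohort_table()].
#' @return data.frame of findings with columns patient_id, field, message,
#'   severity ("error" or "warning"); zero rows when fully valid.
#' @export
validate_cohort <- function(cohort) {
  findings <- list()
  add <- function(f) findings[[length(findings) + 1]] <<- f
  for (i in seq_len(nrow(cohort))) {
    r <- cohort[i, ]
    id <- r$patient_id
    for (col in c("stk1_baseline", "stk1_pre_cycle2", "stk1_post_cycle2_48h")) {
      if (!is.na(r[[col]]) && r[[col]] < 0)
        add(.finding(id, col, "negative concentration"))
    }
    for (col in c("vol_baseline_cm3", "vol_intercycle_cm3", "diam_baseline_cm",
                  "diam_intercycle_cm")) {
      if (!is.na(r[[col]]) && r[[col]] <= 0)
        add(.finding(id, col, "non-positive size measurement"))
    }
    if (is.na(r$stk1_baseline))
      add(.finding(id, "stk1_baseline", "baseline sTK1 required"))
    if (is.na(r$vol_baseline_cm3) && is.na(r$diam_baseline_cm))
      add(.finding(id, "vol_baseline_cm3", "baseline volume or diameter required"))
    if (!is.na(r$outcome) && !(r$outcome %in% .outcome_levels))
      add(.finding(id, "outcome", paste0("unknown outcome: ", r$outcome)))
    if (!is.na(r$outcome) && !is.na(r$residual_volume_cm3)) {
      if (r$residual_volume_cm3 < 0)
        add(.finding(id, "residual_volume_cm3", "negative residual volume"))
      if (r$outcome == "pCR" && r$residual_volume_cm3 != 0)
        add(.finding(id, "residual_volume_cm3", "pCR requires residual volume 0"))
      if (r$outcome != "pCR" && r$residual_volume_cm3 == 0)
        add(.finding(id, "residual_volume_cm3", "non-pCR outcome with residual volume 0"))
    }
    if (!is.na(r$ki67_percent) && (r$ki67_percent < 0 || r$ki67_percent > 100))
      add(.finding(id, "ki67_percent", "Ki67 outside 0-100"))
    for (pair in list(c("diam_baseline_cm", "vol_baseline_cm3"),
                      c("diam_intercycle_cm", "vol_intercycle_cm3"))) {
      d <- r[[pair[1]]]; v <- r[[pair[2]]]
      if (!is.na(d) && !is.na(v) && d > 0 && v > 0) {
        expect <- sphere_volume(d)
        if (abs(v - expect) / expect > 0.01)
          add(.finding(id, pair[2],
                       sprintf("volume %.4g inconsistent with diameter %.4g (sphere: %.4g)",
                               v, d, expect),
                       severity = "warning"))
      }
    }
  }
  if (length(findings) == 0) {
    return(data.frame(patient_id = character(), field = character(),
                      message = character(), severity = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Serialize validation findings as JSON lines
#'
#' @param findings data.frame from [validate_cohort()].
#' @return character vector, one JSON object per finding.
#' @export
findings_jsonl <- function(findings) {
  vapply(seq_len(nrow(findings)), function(i) {
    jsonlite::toJSON(as.list(findings[i, ]), auto_unbox = TRUE)
  }, character(1))
}
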