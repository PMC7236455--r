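#' Quartile assignment by rank blocks
#'
#' Patients are sorted by the stratifying value (ascending), ties broken
#' stably by patient id, and the ranks split into four contiguous blocks,
#' the larger blocks first (sizes differ by at most one; n divisible by 4
#' gives equal groups, e.g. 104 -> 26/26/26/26). Rank-block assignment,
#' rather than comparison against quantile cut-points, guarantees equal
#' group sizes regardless of ties. Boundaries are reported as midpoints
#' between the adjacent straddling values.
#'
#' @param values named numeric vector (names = patient ids), all finite,
#'   length >= 4.
#' @param stratifier label for the stratifying variable.
#' @return list of class `quartile_grouping`: `labels` (named integer
#'   vector in 1..4, in the input's id order), `boundaries` (3 cut values),
#'   `stratifier`, `sizes`.
#' @export
assign_quartiles <- function(values, stratifier = "value") {
  if (length(values) < 4) {
    stop_cellloss("need at least 4 values for quartile assignment",
                  "cellloss_precondition_error")
  }
  if (is.null(names(values)) || any(names(values) == "") || anyDuplicated(names(values))) {
    stop_cellloss("values must be uniquely named by patient id",
                  "cellloss_precondition_error")
  }
  bad <- !is.finite(values)
  if (any(bad)) {
    stop_cellloss(paste0("non-finite value for patient ", names(values)[which(bad)[1]]),
                  "cellloss_precondition_error")
  }
  n <- length(values)
  ord <- order(values, names(values), method = "radix")
  base <- n %/% 4L
  sizes <- base + as.integer(seq_len(4L) <= n %% 4L)  # larger blocks first
  labels_sorted <- rep.int(1:4, times = sizes)
  labels <- integer(n)
  labels[ord] <- labels_sorted
  names(labels) <- names(values)
  cuts <- cumsum(sizes)[1:3]
  sorted_vals <- values[ord]
  boundaries <- (sorted_vals[cuts] + sorted_vals[pmin(cuts + 1L, n)]) / 2
  structure(list(labels = labels, boundaries = unname(boundaries),
                 stratifier = stratifier, sizes = sizes),
            class = "quartile_grouping")
}

#' @export
print.quartile_grouping <- function(x, ...) {
  cat(sprintf("<quartile_grouping> on %s: sizes %s; boundaries %s\n",
              x$stratifier, paste(x$sizes, collapse = "/"),
              paste(signif(x$boundaries, 4), collapse = ", ")))
  invisible(x)
}

#' Descriptive statistics in the study's table layout
#'
#' n, mean, sample standard deviation (n-1 denominator), median, min, max,
#' Q1 (25th percentile), Q3 (75th percentile) and IQR = Q3 - Q1. Quantiles
#' use linear interpolation between order statistics at position
#' (n-1)*p (R type 7); the convention is centralized here and switchable
#' via `type` (the source study used SAS, whose default percentile
#' definition differs; with no patient-level data, no printed quantile can
#' adjudicate the convention).
#'
#' @param values numeric vector, n >= 1, NAs dropped.
#' @param type quantile type passed to [stats::quantile()] (default 7).
#' @return named list of class `summary_stats`.
#' @export
summary_stats <- function(values, type = 7) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    stop_cellloss("cannot summarize an empty vector", "cellloss_precondition_error")
  }
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = type, names = FALSE)
  structure(list(n = length(values),
                 mean = mean(values),
                 std = if (length(values) > 1) stats::sd(values) else 0,
                 median = q[2], min = min(values), max = max(values),
                 q1 = q[1], q3 = q[3], iqr = q[3] - q[1]),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n %d  mean (std) %.4g (%.4g)  median (min;max) %.4g (%.4g;%.4g)  Q1, Q3 (IQR) %.4g, %.4g (%.4g)\n",
              x$n, x$mean, x$std, x$median, x$min, x$max, x$q1, x$q3, x$iqr))
  invisible(x)
}

.is_categorical <- function(v) is.character(v) || is.logical(v) || is.factor(v)

#' Per-quartile descriptive tables
#'
#' Builds the descriptive table: one set of summary statistics per
#' (variable, group) plus a "Total" column. Numeric variables are
#' summarized with [summary_stats()]; categorical covariates as count and
#' percent, the percentage base being the group's non-missing count.
#'
#' @param data data.frame containing `patient_id` and the variables (e.g.
#'   a cohort joined with [compute_metrics()] output).
#' @param grouping a `quartile_grouping` covering every patient in `data`.
#' @param variables character vector of column names to summarize.
#' @return data.frame in long layout: variable, group ("Total","Q1".."Q4"),
#'   and for numeric variables the [summary_stats()] fields; for
#'   categorical variables one row per level with n, count, percent.
#' @export
group_summaries <- function(data, grouping, variables) {
  stopifnot(is.data.frame(data), inherits(grouping, "quartile_grouping"))
  unknown <- setdiff(variables, names(data))
  if (length(unknown) > 0) {
    stop_cellloss(paste0("unknown variable(s): ", paste(unknown, collapse = ", ")),
                  "cellloss_precondition_error")
  }
  if (!all(data$patient_id %in% names(grouping$labels))) {
    stop_cellloss("grouping does not cover all records", "cellloss_precondition_error")
  }
  grp <- grouping$labels[data$patient_id]
  groups <- c(list(Total = rep(TRUE, nrow(data))),
              stats::setNames(lapply(1:4, function(g) grp == g), paste0("Q", 1:4)))
  num_rows <- list(); cat_rows <- list()
  for (v in variables) {
    col <- data[[v]]
    if (.is_categorical(col)) {
      lev <- sort(unique(as.character(col[!is.na(col)])))
      for (gname in names(groups)) {
        sub <- as.character(col[groups[[gname]]])
        base <- sum(!is.na(sub))
        for (l in lev) {
          cnt <- sum(sub == l, na.rm = TRUE)
          cat_rows[[length(cat_rows) + 1]] <- data.frame(
            variable = v, group = gname, level = l, n = base, count = cnt,
            percent = if (base > 0) 100 * cnt / base else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    } else {
      for (gname in names(groups)) {
        sub <- col[groups[[gname]]]
        if (all(is.na(sub))) next
        s <- summary_stats(sub)
        num_rows[[length(num_rows) + 1]] <- data.frame(
          variable = v, group = gname, n = s$n, mean = s$mean, std = s$std,
          median = s$median, min = s$min, max = s$max, q1 = s$q1, q3 = s$q3,
          iqr = s$iqr, stringsAsFactors = FALSE)
      }
    }
  }
  list(numeric = if (length(num_rows)) do.call(rbind, num_rows) else NULL,
       categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else NULL)
}
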