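#' @title ROC analysis and confusion-matrix tools
#'
#' @description
#' Empirical ROC curve and AUC for discriminating pathologic complete
#' response from residual tumour, Youden-optimal cut-off selection, and
#' audit tools that reconstruct the integer confusion matrices behind
#' rounded printed sensitivities, specificities and predictive values.
#' Orientation throughout: a higher score (cell-loss metric) predicts the
#' positive class (pCR); a patient is test-positive when score >= cutoff.
#'
#' @name cellloss-roc
NULL

.check_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_cellloss("scores and labels must have equal length", "cellloss_precondition_error")
  }
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (sum(labels) == 0 || sum(!labels) == 0) {
    stop_cellloss("need at least one positive and one negative label",
                  "cellloss_precondition_error")
  }
  list(scores = scores, labels = labels)
}

#' Empirical ROC curve and AUC
#'
#' Sweeps every distinct score as an inclusive threshold (test-positive
#' iff score >= threshold), producing points from (0,0) to (1,1); the AUC
#' is the trapezoidal area, which with this sweep equals the tie-corrected
#' rank (Mann-Whitney) statistic: ties between a positive and a negative
#' count one half.
#'
#' @param scores numeric vector (higher = more indicative of the positive
#'   class). May be named by patient id.
#' @param labels logical (or coercible) vector, TRUE = positive class.
#' @return list of class `roc_curve`: `points` (data.frame threshold, fpr,
#'   tpr), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  d <- .check_labels(scores, labels)
  scores <- d$scores; labels <- d$labels
  n_pos <- sum(labels); n_neg <- sum(!labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1) {
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.3f (%d positives, %d negatives, %d points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

confusion_summary <- function(tp, fp, fn, tn, cutoff = NA_real_) {
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, cutoff = cutoff,
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 ppv = rate(tp, tp + fp),
                 npv = rate(tn, tn + fn)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("tp %d fp %d fn %d tn %d%s\n", x$tp, x$fp, x$fn, x$tn,
              if (!is.na(x$cutoff)) sprintf("  (cutoff %.4g)", x$cutoff) else ""))
  cat(sprintf("  sens %.3f  spec %.3f  PPV %.1f%%  NPV %.1f%%\n",
              x$sensitivity, x$specificity, 100 * x$ppv, 100 * x$npv))
  invisible(x)
}

#' @export
as.list.confusion_summary <- function(x, ...) unclass(x)

#' Confusion summary at a fixed cut-off
#'
#' @inheritParams roc_curve
#' @param cutoff threshold; test-positive iff score >= cutoff.
#' @return a `confusion_summary` with tp/fp/fn/tn and derived rates
#'   (sensitivity, specificity, PPV, NPV; NA-flagged when a denominator
#'   is zero).
#' @export
evaluate_cutoff <- function(scores, labels, cutoff) {
  d <- .check_labels(scores, labels)
  pos <- d$scores >= cutoff
  confusion_summary(tp = sum(pos & d$labels), fp = sum(pos & !d$labels),
                    fn = sum(!pos & d$labels), tn = sum(!pos & !d$labels),
                    cutoff = cutoff)
}

#' Youden-optimal cut-off
#'
#' Scans the midpoints between adjacent distinct scores (plus the
#' all-positive and all-negative extremes) and returns the cutoff
#' maximizing Youden's J = sensitivity + specificity - 1, ties broken
#' toward higher specificity (then the higher cutoff).
#'
#' @inheritParams roc_curve
#' @return list: `cutoff`, `youden` (the J value), `confusion`
#'   (a `confusion_summary`).
#' @export
youden_cutoff <- function(scores, labels) {
  d <- .check_labels(scores, labels)
  s <- sort(unique(d$scores))
  candidates <- if (length(s) > 1) {
    c(s[1] - 1, (utils::head(s, -1) + utils::tail(s, -1)) / 2, s[length(s)] + 1)
  } else {
    c(s - 1, s + 1)
  }
  best <- NULL
  for (cut in candidates) {
    cs <- evaluate_cutoff(d$scores, d$labels, cut)
    j <- cs$sensitivity + cs$specificity - 1
    if (is.null(best) || j > best$youden + 1e-12 ||
        (abs(j - best$youden) <= 1e-12 &&
         (cs$specificity > best$confusion$specificity + 1e-12 ||
          (abs(cs$specificity - best$confusion$specificity) <= 1e-12 &&
           cut > best$cutoff)))) {
      best <- list(cutoff = cut, youden = j, confusion = cs)
    }
  }
  best
}

#' Reconstruct an integer confusion matrix from rounded printed rates
#'
#' Given the class margins and the printed (rounded) sensitivity and
#' 1 - specificity, recovers the implied integer matrix: tp = round(sens *
#' n_pos), fp = round((1 - spec) * n_neg) (half-up), the remaining cells
#' by the margins. This makes printed predictive values auditable: e.g.
#' with 24 responders and 80 non-responders, sensitivity 0.71 and
#' 1 - specificity 0.31 give (tp, fp, fn, tn) = (17, 25, 7, 55), hence
#' PPV 17/42 = 40.5% and NPV 55/62 = 88.7%.
#'
#' @param n_pos,n_neg class sizes (>= 1).
#' @param sensitivity,one_minus_specificity rounded rates in [0, 1].
#' @return a `confusion_summary` (cutoff absent).
#' @export
reconstruct_confusion <- function(n_pos, n_neg, sensitivity, one_minus_specificity) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  if (sensitivity < 0 || sensitivity > 1 ||
      one_minus_specificity < 0 || one_minus_specificity > 1) {
    stop_cellloss("rates must lie in [0, 1]", "cellloss_domain_error")
  }
  tp <- round_half_up(sensitivity * n_pos)
  fp <- round_half_up(one_minus_specificity * n_neg)
  if (tp > n_pos || fp > n_neg) {
    stop_cellloss("rounded counts exceed the class margins", "cellloss_domain_error")
  }
  confusion_summary(tp = as.integer(tp), fp = as.integer(fp),
                    fn = as.integer(n_pos - tp), tn = as.integer(n_neg - fp))
}

.rate_value <- function(cs, rate) {
  switch(rate,
         sensitivity = cs$sensitivity,
         specificity = cs$specificity,
         one_minus_specificity = 1 - cs$specificity,
         ppv = cs$ppv,
         npv = cs$npv,
         stop_cellloss(paste0("unknown rate: ", rate), "cellloss_domain_error"))
}

#' Enumerate all confusion matrices consistent with rounded printed rates
#'
#' Exhausts the (n_pos + 1) x (n_neg + 1) grid of integer matrices with
#' the given class margins and keeps those whose derived rates, expressed
#' in percent and rounded half-up to `digits` decimals, match every
#' constraint. An empty constraint set returns the full grid; matrices
#' with an undefined constrained rate (zero denominator) are excluded.
#'
#' @param n_pos,n_neg class sizes (>= 1).
#' @param constraints named numeric vector/list, names among
#'   "sensitivity", "specificity", "one_minus_specificity", "ppv", "npv",
#'   values in percent as printed (e.g. c(ppv = 77.8, npv = 83.3)).
#' @param digits decimals of the printed percentages (default 1).
#' @return list of `confusion_summary` objects (possibly empty).
#' @export
enumerate_consistent_matrices <- function(n_pos, n_neg, constraints = NULL,
                                          digits = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  constraints <- unlist(constraints)
  out <- list()
  for (tp in 0:n_pos) {
    for (fp in 0:n_neg) {
      cs <- confusion_summary(tp, fp, n_pos - tp, n_neg - fp)
      ok <- TRUE
      for (nm in names(constraints)) {
        v <- .rate_value(cs, nm)
        if (is.na(v) || round_half_up(100 * v, digits) != constraints[[nm]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) out[[length(out) + 1]] <- cs
    }
  }
  out
}
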