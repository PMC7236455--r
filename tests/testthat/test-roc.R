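# O(n^2) pair-counting oracle: 1 per correctly ordered positive/negative
# pair, 1/2 per tie.
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

test_that("ROC endpoints: perfect separation and pure ties", {
  s <- c(1, 2, 3, 10, 11, 12)
  l <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(roc_curve(s, l)$auc, 1)
  expect_equal(roc_curve(rep(4, 6), l)$auc, 0.5)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), class = "cellloss_precondition_error")
})

test_that("trapezoidal AUC equals the pair-counting oracle (with ties)", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    s <- sample(round(rnorm(n), 1)) # rounding forces ties
    l <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    rc <- roc_curve(s, l)
    expect_equal(rc$auc, auc_pair_oracle(s, l), tolerance = 1e-12)
    # and equals the tie-corrected rank statistic
    r <- rank(s)
    u <- (mean(r[l]) - (sum(l) + 1) / 2) * sum(l) / (sum(l) * sum(!l))
    expect_equal(rc$auc, u, tolerance = 1e-12)
  }
})

test_that("AUC of negated tie-free scores is the complement", {
  set.seed(32)
  s <- rnorm(20); l <- c(rep(TRUE, 8), rep(FALSE, 12))
  expect_equal(roc_curve(s, l)$auc + roc_curve(-s, l)$auc, 1)
})

test_that("AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(33)
  s <- round(rnorm(40), 1); l <- runif(40) < 0.35
  l[1:2] <- c(TRUE, FALSE)
  expect_equal(roc_curve(s, l)$auc,
               as.numeric(suppressMessages(pROC::auc(pROC::roc(l, s, quiet = TRUE)))),
               tolerance = 1e-12)
})

test_that("evaluate_cutoff counts the toy confusion matrix by hand", {
  s <- c(2, 4, 6, 8); l <- c(FALSE, FALSE, TRUE, TRUE)
  cs <- evaluate_cutoff(s, l, 5)
  expect_equal(c(cs$tp, cs$fp, cs$fn, cs$tn), c(2, 0, 0, 2))
  lo <- evaluate_cutoff(s, l, 0)
  expect_equal(c(lo$sensitivity, lo$specificity), c(1, 0))
  hi <- evaluate_cutoff(s, l, 100)
  expect_equal(c(hi$sensitivity, hi$specificity), c(0, 1))
})

test_that("evaluate_cutoff at the sweep thresholds reproduces the ROC points", {
  set.seed(34)
  s <- round(rnorm(25), 1); l <- runif(25) < 0.4
  l[1:2] <- c(TRUE, FALSE)
  rc <- roc_curve(s, l)
  for (i in seq_len(nrow(rc$points))) {
    thr <- rc$points$threshold[i]
    if (!is.finite(thr)) next
    cs <- evaluate_cutoff(s, l, thr)
    expect_equal(1 - cs$specificity, rc$points$fpr[i])
    expect_equal(cs$sensitivity, rc$points$tpr[i])
  }
})

test_that("Youden cutoff matches an exhaustive threshold scan", {
  s <- c(1, 2, 3, 10, 11, 12)
  l <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  y <- youden_cutoff(s, l)
  expect_equal(y$youden, 1)
  expect_equal(y$cutoff, 6.5)
  expect_equal(youden_cutoff(rep(3, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))$youden, 0)
  set.seed(35)
  for (i in 1:10) {
    s <- round(rnorm(10), 1); l <- runif(10) < 0.5
    l[1:2] <- c(TRUE, FALSE)
    y <- youden_cutoff(s, l)
    # oracle: scan a fine grid of cutoffs; no cutoff can beat the reported J
    grid <- sort(unique(c(s - 1e-6, s + 1e-6, seq(min(s) - 1, max(s) + 1, by = 0.01))))
    js <- vapply(grid, function(cut) {
      cs <- evaluate_cutoff(s, l, cut)
      cs$sensitivity + cs$specificity - 1
    }, numeric(1))
    expect_equal(y$youden, max(js), tolerance = 1e-9)
  }
})

test_that("likelihood-ratio identity links PPV to sensitivity and specificity", {
  set.seed(36)
  for (i in 1:15) {
    n_pos <- sample(3:20, 1); n_neg <- sample(3:40, 1)
    tp <- sample(0:n_pos, 1); fp <- sample(0:n_neg, 1)
    cs <- reconstruct_confusion(n_pos, n_neg, tp / n_pos, fp / n_neg)
    if (is.na(cs$ppv) || cs$ppv %in% c(0, 1) || is.na(cs$specificity) ||
        cs$specificity == 1) next
    lhs <- cs$ppv / (1 - cs$ppv)
    rhs <- (cs$sensitivity / (1 - cs$specificity)) * (n_pos / n_neg)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("reconstruction recovers the printed 48 h predictive values", {
  cs <- reconstruct_confusion(24, 80, 0.71, 0.31)
  expect_equal(c(cs$tp, cs$fp, cs$fn, cs$tn), c(17, 25, 7, 55))
  expect_equal(round_half_up(100 * cs$ppv, 1), 40.5)
  expect_equal(round_half_up(100 * cs$npv, 1), 88.7)
  diag <- reconstruct_confusion(10, 10, 1.0, 0.0)
  expect_equal(c(diag$tp, diag$fp, diag$fn, diag$tn), c(10, 0, 0, 10))
  expect_equal(c(diag$ppv, diag$npv), c(1, 1))
  expect_error(reconstruct_confusion(10, 10, 1.5, 0), class = "cellloss_domain_error")
})

test_that("consistent-matrix enumeration exhausts and filters the grid", {
  all9 <- enumerate_consistent_matrices(2, 2)
  expect_length(all9, 9)
  none <- enumerate_consistent_matrices(5, 5,
                                        c(ppv = 100, sensitivity = 0))
  expect_length(none, 0)
  one <- enumerate_consistent_matrices(15, 42, c(ppv = 77.8, npv = 83.3))
  expect_length(one, 1)
  expect_equal(c(one[[1]]$tp, one[[1]]$fp, one[[1]]$fn, one[[1]]$tn),
               c(7, 2, 8, 40))
})
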