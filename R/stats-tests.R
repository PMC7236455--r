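#' @title Exact and classical tests used by the pipeline
#'
#' @description
#' The pipeline's inferential core: Fisher's exact test on 2 x k tables
#' (the Freeman-Halton extension, by full enumeration of the conditional
#' table space), the Wilcoxon signed-rank and rank-sum tests with exact
#' small-sample enumeration, one-way ANOVA, and Spearman rank correlation.
#' Each returns a `test_result`: method label, statistic, two-sided
#' p-value, n used, and a degenerate flag for edge cases.
#'
#' @name cellloss-tests
NULL

test_result <- function(method, statistic, p_value, n_used, degenerate = FALSE) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n_used = n_used, degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %s, p = %.4g (n = %d%s)\n", x$method,
              if (is.null(x$statistic) || is.na(x$statistic)) "-" else signif(x$statistic, 4),
              x$p_value, x$n_used, if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

#' @export
as.list.test_result <- function(x, ...) unclass(x)

#' Build a 2 x k contingency table
#'
#' @param counts 2 x k matrix of non-negative integers (k >= 2).
#' @param row_labels,col_labels optional dimension labels.
#' @return matrix of class `contingency_table`.
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || ncol(counts) < 2) {
    stop_cellloss("contingency table must be 2 x k with k >= 2", "cellloss_domain_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_cellloss("counts must be non-negative integers", "cellloss_domain_error")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  class(counts) <- c("contingency_table", class(counts))
  counts
}

# All compositions of `total` over k cells with per-cell caps; k x M matrix.
.compositions <- function(total, caps, limit) {
  k <- length(caps)
  if (k == 1) {
    if (total > caps[1]) return(matrix(integer(0), nrow = 1))
    return(matrix(total, nrow = 1))
  }
  lo <- max(0L, total - sum(caps[-1]))
  hi <- min(caps[1], total)
  if (lo > hi) return(matrix(integer(0), nrow = k))
  parts <- lapply(lo:hi, function(a) {
    rest <- .compositions(total - a, caps[-1], limit)
    rbind(matrix(a, nrow = 1, ncol = ncol(rest)), rest)
  })
  out <- do.call(cbind, parts)
  if (ncol(out) > limit) {
    stop_cellloss(sprintf("table space exceeds enumeration limit (%g)", limit),
                  "cellloss_enumeration_limit")
  }
  out
}

#' Fisher's exact test for 2 x k tables (Freeman-Halton)
#'
#' Enumerates every 2 x k table with the observed margins; under the null,
#' table probabilities follow the multivariate hypergeometric distribution,
#' and the two-sided p-value is the total probability of tables no more
#' likely than the observed one (probability-mass criterion, with relative
#' tolerance 1e-12 when comparing probabilities). For k = 2 this is the
#' usual two-sided Fisher exact test.
#'
#' @param table 2 x k matrix or [contingency_table()].
#' @param limit maximum number of enumerated tables (default 1e7); the
#'   test errors rather than silently approximating beyond it.
#' @return a `test_result` (statistic = probability of the observed table).
#' @export
fisher_exact_2xk <- function(table, limit = 1e7) {
  tab <- contingency_table(table)
  r1 <- sum(tab[1, ]); cs <- colSums(tab); N <- sum(tab)
  if (r1 == 0 || sum(tab[2, ]) == 0 || any(cs == 0)) {
    # a zero margin leaves no (or a fully determined) conditional table space
    return(test_result("Fisher exact (2xk)", statistic = 1, p_value = 1,
                       n_used = N, degenerate = TRUE))
  }
  comps <- .compositions(r1, cs, limit)
  logp <- colSums(lchoose(cs, comps)) - lchoose(N, r1)
  logp_obs <- sum(lchoose(cs, tab[1, ])) - lchoose(N, r1)
  p <- sum(exp(logp)[logp <= logp_obs + log1p(1e-12)])
  test_result("Fisher exact (2xk)", statistic = exp(logp_obs),
              p_value = min(1, p), n_used = N)
}

# Distribution of all enumerated table probabilities (exported for
# conservation checks and audit).
#' Probabilities of all 2 x k tables with the given margins
#' @param table 2 x k matrix; margins are taken from it.
#' @param limit enumeration cap.
#' @return numeric vector of multivariate-hypergeometric probabilities,
#'   one per table with the observed margins.
#' @export
fisher_table_probabilities <- function(table, limit = 1e7) {
  tab <- contingency_table(table)
  r1 <- sum(tab[1, ]); cs <- colSums(tab); N <- sum(tab)
  comps <- .compositions(r1, cs, limit)
  exp(colSums(lchoose(cs, comps)) - lchoose(N, r1))
}

#' Wilcoxon test (signed-rank or rank-sum), two-sided
#'
#' Paired: signed-rank on the differences, zero differences dropped,
#' midranks for ties; exact enumeration of all 2^n sign assignments when
#' the effective n <= 12, otherwise normal approximation with tie and
#' continuity correction. Unpaired: rank-sum of `x` in the pooled sample;
#' exact enumeration of rank subsets when min(n, m) <= 10 and the subset
#' space is tractable (<= 2e5 subsets), otherwise the corrected normal
#' approximation. Exact p-values are 2 * min(lower tail, upper tail),
#' capped at 1.
#'
#' @param x,y numeric samples (equal length when `paired`).
#' @param paired logical.
#' @return a `test_result` (statistic: V for signed-rank, W = rank-sum of
#'   x minus its minimum, i.e. the Mann-Whitney U, for unpaired).
#' @export
wilcoxon_test <- function(x, y, paired = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (paired) {
    if (length(x) != length(y)) {
      stop_cellloss("paired samples must have equal length", "cellloss_precondition_error")
    }
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) {
      return(test_result("Wilcoxon signed-rank", statistic = 0, p_value = 1,
                         n_used = length(x), degenerate = TRUE))
    }
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    if (n <= 12) {
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
      stats <- as.vector(signs %*% r)
      p <- 2 * min(mean(stats <= v + 1e-9), mean(stats >= v - 1e-9))
      return(test_result("Wilcoxon signed-rank (exact)", statistic = v,
                         p_value = min(1, p), n_used = n))
    }
    ev <- n * (n + 1) / 4
    ties <- table(r)
    varv <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - ev - sign(v - ev) * 0.5) / sqrt(varv)
    p <- 2 * stats::pnorm(-abs(z))
    return(test_result("Wilcoxon signed-rank (normal approx.)", statistic = v,
                       p_value = min(1, p), n_used = n))
  }
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) {
    stop_cellloss("both samples must be non-empty", "cellloss_precondition_error")
  }
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n)]) - n * (n + 1) / 2  # Mann-Whitney U of x
  N <- n + m
  small <- min(n, m)
  if (small <= 10 && choose(N, small) <= 2e5) {
    idx <- utils::combn(N, n)
    stats <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    p <- 2 * min(mean(stats <= w + 1e-9), mean(stats >= w - 1e-9))
    return(test_result("Wilcoxon rank-sum (exact)", statistic = w,
                       p_value = min(1, p), n_used = N))
  }
  ties <- table(r)
  ew <- n * m / 2
  varw <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (w - ew - sign(w - ew) * 0.5) / sqrt(varw)
  p <- 2 * stats::pnorm(-abs(z))
  test_result("Wilcoxon rank-sum (normal approx.)", statistic = w,
              p_value = min(1, p), n_used = N)
}

#' One-way analysis of variance
#'
#' F = MS_between / MS_within with (g - 1, n - g) degrees of freedom.
#' Degenerate handling: zero within-group variance gives p = 0 when group
#' means differ and p = 1 when they are all equal.
#'
#' @param groups list of numeric samples (>= 2 groups, each non-empty,
#'   total n > number of groups).
#' @return a `test_result` (statistic = F).
#' @export
anova_oneway <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[lengths(groups) > 0]
  g <- length(groups)
  n <- sum(lengths(groups))
  if (g < 2 || n <= g) {
    stop_cellloss("need >= 2 non-empty groups and total n > number of groups",
                  "cellloss_precondition_error")
  }
  all_v <- unlist(groups)
  grand <- mean(all_v)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(lengths(groups) * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw == 0) {
    if (ssb == 0) {
      return(test_result("one-way ANOVA", statistic = 0, p_value = 1,
                         n_used = n, degenerate = TRUE))
    }
    return(test_result("one-way ANOVA", statistic = Inf, p_value = 0,
                       n_used = n, degenerate = TRUE))
  }
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  p <- stats::pf(f, g - 1, n - g, lower.tail = FALSE)
  test_result("one-way ANOVA", statistic = f, p_value = p, n_used = n)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks; the two-sided p-value uses
#' the t approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2
#' degrees of freedom. Constant input leaves rho undefined and is flagged
#' degenerate rather than raising.
#'
#' @param x,y numeric samples of equal length >= 3 (pairwise-complete).
#' @return a `test_result` (statistic = rho).
#' @export
spearman_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y) || length(x) < 3) {
    stop_cellloss("need equal-length samples with n >= 3", "cellloss_precondition_error")
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(test_result("Spearman correlation", statistic = NA_real_,
                       p_value = NA_real_, n_used = length(x), degenerate = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  test_result("Spearman correlation", statistic = rho, p_value = p, n_used = n)
}
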