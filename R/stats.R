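#' @name stats-tests
#' @title Statistical machinery
#'
#' @description
#' The nonstandard piece here is the exact paired signed-rank test, computed
#' by full enumeration of sign assignments (feasible up to n = 25, where
#' 2^25 assignments reduce to a rank-sum count distribution). The remaining
#' tests the analyses rely on (Fisher's exact, chi-square, Friedman with
#' Nemenyi post hoc, Mann-Whitney U, Spearman, Kolmogorov-Smirnov) are thin
#' result-normalizing adapters over the standard routines; every result comes
#' back as a uniform `test_result` list (statistic, p, n, method, corrected).
NULL

.test_result <- function(statistic, p, n, method, corrected = FALSE, ...) {
  structure(list(statistic = unname(statistic), p = unname(min(max(p, 0), 1)),
                 n = n, method = method, corrected = corrected, ...),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic), ", p = ",
      format.pval(x$p, digits = 3), ", n = ", paste(x$n, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Number of subsets of the (possibly tied, doubled-to-integer) ranks whose sum
# is <= target, by polynomial DP over achievable sums.
.count_rank_sums_le <- function(ranks2, target2) {
  max_sum <- sum(ranks2)
  counts <- numeric(max_sum + 1L)       # counts[s+1] = #subsets with sum s
  counts[1L] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts[seq_len(max_sum + 1L - r)])
    counts <- counts + shifted
  }
  sum(counts[seq_len(min(target2, max_sum) + 1L)])
}

#' Exact paired signed-rank test
#'
#' Zero differences are dropped; ties get midranks. For n <= `exact_limit`
#' with untied ranks the two-sided p is exact: the signed-rank statistic
#' W = min(sum of positive ranks, sum of negative ranks) is referred to the
#' enumeration of all 2^n sign assignments, p = 2 P(W+ <= W) capped at 1.
#' Midranks are enumerated the same way (sums doubled to stay integral);
#' beyond `exact_limit` a normal approximation with tie correction is used.
#'
#' @param differences numeric paired differences.
#' @param exact_limit largest n for exact enumeration.
#' @return `test_result` with `statistic` (W, the smaller signed-rank sum).
#' @export
exact_signed_rank <- function(differences, exact_limit = 25L) {
  d <- differences[differences != 0]
  if (length(d) == 0L) stop("all differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0]); w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)
  has_ties <- anyDuplicated(r) > 0L
  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))      # midranks doubled -> integers
    count <- .count_rank_sums_le(ranks2, as.integer(round(2 * W)))
    p <- min(1, 2 * count / 2^n)
    return(.test_result(W, p, n, method = if (has_ties)
      "exact signed-rank (midranks)" else "exact signed-rank"))
  }
  mu <- n * (n + 1) / 4
  tie_sizes <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_sizes^3 - tie_sizes) / 48
  z <- (w_pos - mu) / sqrt(sigma2)
  .test_result(W, 2 * pnorm(-abs(z)), n, method = "signed-rank (normal approx.)")
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional (hypergeometric) two-sided p; the reported odds ratio is the
#' sample odds ratio ad/bc. A zero margin gives p = 1 with an undefined OR.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return `test_result` with `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(.test_result(NA_real_, 1, sum(table), "Fisher exact",
                        odds_ratio = NA_real_))
  }
  ft <- fisher.test(table)
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  .test_result(or, ft$p.value, sum(table), "Fisher exact", odds_ratio = or)
}

#' Friedman test with Nemenyi post hoc comparisons
#'
#' Friedman chi-square on within-subject ranks; when it is significant at
#' `alpha`, all condition pairs are compared with the Nemenyi test: the
#' studentized-range statistic on mean rank differences,
#' `q = |Ri - Rj| / sqrt(k (k + 1) / (12 n))`, referred to the range
#' distribution with infinite df.
#'
#' @param block_matrix subjects x conditions numeric matrix.
#' @param alpha gate for running the post hoc comparisons.
#' @return `test_result` with `posthoc` (data.frame of pairwise q and p, or
#'   NULL).
#' @export
friedman_nemenyi <- function(block_matrix, alpha = 0.05) {
  m <- as.matrix(block_matrix)
  if (ncol(m) < 3L) stop("need >= 3 conditions")
  if (all(apply(m, 1L, function(r) length(unique(r)) == 1L))) {
    stop("all rows constant: ranks undefined")
  }
  ft <- friedman.test(m)
  n <- nrow(m); k <- ncol(m)
  posthoc <- NULL
  if (ft$p.value < alpha) {
    ranks <- t(apply(m, 1L, rank))
    mean_rank <- colMeans(ranks)
    se <- sqrt(k * (k + 1) / (12 * n))
    pairs <- utils::combn(k, 2L)
    posthoc <- data.frame(
      i = pairs[1L, ], j = pairs[2L, ],
      q = abs(mean_rank[pairs[1L, ]] - mean_rank[pairs[2L, ]]) / se,
      stringsAsFactors = FALSE)
    posthoc$p <- ptukey(posthoc$q * sqrt(2), nmeans = k, df = Inf,
                        lower.tail = FALSE)
  }
  .test_result(unname(ft$statistic), ft$p.value, n, "Friedman",
               posthoc = posthoc)
}

#' Bonferroni adjustment
#'
#' Multiplies each p by `m` and truncates at 1.00.
#'
#' @param p_values numeric p-values.
#' @param m number of comparisons (>= length(p_values)).
#' @return adjusted p-values.
#' @export
adjust_bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) stop("m must be >= number of p-values")
  pmin(1, p_values * m)
}

#' Wilson score confidence interval for a proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return c(lower, upper).
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Mann-Whitney U test (adapter)
#'
#' @param x,y numeric samples.
#' @return `test_result` (statistic is the U of `x`).
#' @export
mann_whitney_u <- function(x, y) {
  wt <- suppressWarnings(wilcox.test(x, y))
  .test_result(unname(wt$statistic), wt$p.value, c(length(x), length(y)),
               "Mann-Whitney U")
}

#' Spearman rank correlation (adapter)
#'
#' @param x,y numeric vectors.
#' @return `test_result` with `rho`.
#' @export
spearman_cor <- function(x, y) {
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  .test_result(unname(ct$estimate), ct$p.value, length(x), "Spearman",
               rho = unname(ct$estimate))
}

#' Kolmogorov-Smirnov test (adapter)
#'
#' One-sample against a distribution function, or two-sample when `y` is
#' numeric.
#'
#' @param x numeric sample.
#' @param y numeric sample, or a cdf like `pnorm`.
#' @param ... passed to [stats::ks.test()].
#' @return `test_result`.
#' @export
ks_adapter <- function(x, y = "pnorm", ...) {
  kt <- suppressWarnings(ks.test(x, y, ...))
  .test_result(unname(kt$statistic), kt$p.value, length(x), "Kolmogorov-Smirnov")
}

#' Chi-square test on a contingency table (adapter)
#'
#' @param table contingency matrix.
#' @param correct continuity correction (off by default, matching large-sample
#'   contingency use).
#' @return `test_result`.
#' @export
chisq_adapter <- function(table, correct = FALSE) {
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  .test_result(unname(ct$statistic), ct$p.value, sum(table), "chi-square")
}
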