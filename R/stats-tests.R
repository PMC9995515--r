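# Group-comparison statistics: omnibus, post-hoc, summary-statistic and
# rank tests, plus FDR adjustment.

pull_two <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (any(!is.finite(v))) abort_bad_input("Values must be finite.")
  list(v = v, g = g)
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based one-way comparison of two or more groups; the statistic H is
#' computed on mid-ranks with tie correction and referred to a chi-squared
#' distribution with k - 1 degrees of freedom. When every observation is
#' identical the test is degenerate and returns H = 0, p = 1.
#'
#' @param data Data frame with one row per observation.
#' @param value Column of values (tidy-eval).
#' @param group Column of group labels (tidy-eval).
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(data, value, group) {
  d <- pull_two(data, {{ value }}, {{ group }})
  if (nlevels(d$g) < 2) abort_bad_input("Need at least 2 groups.")
  if (length(d$v) < 3) abort_bad_input("Need at least 3 observations in total.")
  if (length(unique(d$v)) == 1) {
    return(tibble::tibble(
      statistic = 0, df = nlevels(d$g) - 1L, p_value = 1, n = length(d$v)
    ))
  }
  kt <- stats::kruskal.test(d$v, d$g)
  tibble::tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value,
    n = length(d$v)
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate across a
#' family of tests (one band by condition by feature family in this
#' pipeline, e.g. the 31 channels or the 465 coherence pairs). Adjusted
#' values are order-preserving, never below the raw p, and capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort_bad_input("p-values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

#' Tukey HSD post-hoc pairwise comparisons
#'
#' All-pairs comparison of group means with studentized-range p-values,
#' run after a significant omnibus test. `direction` is the sign of
#' `mean(group_a) - mean(group_b)`. A rank-based Dunn z-test alternative is
#' available via `method = "dunn"` for users who prefer a post hoc
#' consistent with the rank-based omnibus.
#'
#' @param data Data frame with one row per observation.
#' @param value,group Columns of values and group labels (tidy-eval).
#' @param method `"tukey"` (default) or `"dunn"`.
#' @return Tibble with one row per unordered pair: `group_a`, `group_b`,
#'   `diff` (a minus b, mean or mean-rank difference), `p_adj`,
#'   `direction`.
#' @export
posthoc_tukey <- function(data, value, group, method = c("tukey", "dunn")) {
  method <- match.arg(method)
  d <- pull_two(data, {{ value }}, {{ group }})
  if (nlevels(d$g) < 2) abort_bad_input("Need at least 2 groups.")
  if (any(table(d$g) < 2)) abort_bad_input("Each group needs at least 2 observations.")
  if (method == "tukey") {
    tukey_hsd(d$v, d$g)
  } else {
    dunn_test(d$v, d$g)
  }
}

# Tukey HSD from its definition: studentized range of pairwise mean
# differences against the pooled within-group mean square.
tukey_hsd <- function(v, g) {
  g <- droplevels(g)
  lev <- levels(g)
  k <- length(lev)
  ns <- c(tapply(v, g, length))
  means <- c(tapply(v, g, mean))
  n <- length(v)
  mse <- sum((v - means[g])^2) / (n - k)
  if (mse <= 0) {
    abort_degenerate("Zero within-group variance everywhere; Tukey HSD undefined.")
  }
  combs <- utils::combn(lev, 2)
  a <- combs[2, ] # "later-earlier" ordering, as in stats::TukeyHSD
  b <- combs[1, ]
  diff <- unname(means[a] - means[b])
  se <- unname(sqrt(mse / 2 * (1 / ns[a] + 1 / ns[b])))
  p <- stats::ptukey(abs(diff) / se, k, n - k, lower.tail = FALSE)
  tibble::tibble(
    group_a = a, group_b = b,
    diff = diff, p_adj = p, direction = sign(diff)
  )
}

# Dunn's rank-based pairwise z-tests with tie correction (unadjusted p).
dunn_test <- function(v, g) {
  g <- droplevels(g)
  r <- rank(v)
  n <- length(v)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v_all <- n * (n + 1) / 12 - tie_term
  mean_ranks <- c(tapply(r, g, mean))
  ns <- c(tapply(r, g, length))
  combs <- utils::combn(levels(g), 2)
  a <- combs[2, ] # "later-earlier" ordering, as in stats::TukeyHSD
  b <- combs[1, ]
  diff <- unname(mean_ranks[a] - mean_ranks[b])
  z <- diff / unname(sqrt(v_all * (1 / ns[a] + 1 / ns[b])))
  tibble::tibble(
    group_a = a, group_b = b,
    diff = diff, p_adj = 2 * stats::pnorm(-abs(z)), direction = sign(diff)
  )
}

#' Two-sample pooled t-test from summary statistics
#'
#' Recomputes the independent-samples pooled-variance t-test from printed
#' group means, SDs and sizes, as needed to verify published demographic
#' tables. The statistic is `(mean2 - mean1) / se` with
#' `df = n1 + n2 - 2` and a two-sided p-value.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return One-row tibble: `estimate` (mean2 - mean1), `statistic`, `df`,
#'   `p_value`.
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort_bad_input("Both groups need n >= 2.")
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0)) {
    abort_degenerate("SDs must be non-negative and not both zero.")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean2 - mean1) / se
  tibble::tibble(
    estimate = mean2 - mean1,
    statistic = t,
    df = df,
    p_value = 2 * stats::pt(-abs(t), df)
  )
}

#' One-way ANOVA from summary statistics
#'
#' Between- and within-group mean squares reconstructed from group means,
#' SDs and sizes; `F = MSB / MSW` with `k - 1` and `N - k` degrees of
#' freedom. For two groups, F equals the square of the pooled t statistic.
#'
#' @param means,sds,ns Vectors of group means, SDs and sizes (length k).
#' @return One-row tibble: `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k) {
    abort_bad_input("`means`, `sds`, `ns` must have equal length >= 2.")
  }
  if (any(ns < 2)) abort_bad_input("Each group needs n >= 2.")
  n_total <- sum(ns)
  grand <- sum(ns * means) / n_total
  msb <- sum(ns * (means - grand)^2) / (k - 1)
  msw <- sum((ns - 1) * sds^2) / (n_total - k)
  if (msw <= 0) abort_degenerate("Zero within-group variance; F undefined.")
  f <- msb / msw
  tibble::tibble(
    statistic = f,
    df1 = k - 1,
    df2 = n_total - k,
    p_value = stats::pf(f, k - 1, n_total - k, lower.tail = FALSE)
  )
}

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test reporting `U = min(U1, U2)`. The p-value is
#' exact (null distribution of the rank sum) when the samples are free of
#' ties and `n1 * n2 <= 400`, and otherwise uses the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param data Data frame with one row per observation.
#' @param value,group Columns of values and the two-level group labels
#'   (tidy-eval).
#' @return One-row tibble: `statistic` (U), `p_value`, `n1`, `n2`,
#'   `exact`.
#' @export
mann_whitney_u <- function(data, value, group) {
  d <- pull_two(data, {{ value }}, {{ group }})
  if (nlevels(d$g) != 2) abort_bad_input("Need exactly 2 groups.")
  x <- d$v[d$g == levels(d$g)[1]]
  y <- d$v[d$g == levels(d$g)[2]]
  if (!length(x) || !length(y)) abort_bad_input("Both samples must be non-empty.")
  n1 <- length(x)
  n2 <- length(y)
  has_ties <- any(duplicated(c(x, y)))
  exact <- !has_ties && n1 * n2 <= 400
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  u1 <- unname(wt$statistic)
  tibble::tibble(
    statistic = min(u1, n1 * n2 - u1),
    p_value = wt$p.value,
    n1 = n1,
    n2 = n2,
    exact = exact
  )
}

#' Pearson chi-squared test for a contingency table
#'
#' Pearson's chi-squared without continuity correction;
#' `df = (rows - 1) * (cols - 1)`.
#'
#' @param table Matrix of non-negative counts with at least 2 rows and 2
#'   columns and no all-zero row or column margin.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_squared_contingency <- function(table) {
  if (!is.matrix(table) || nrow(table) < 2 || ncol(table) < 2) {
    abort_bad_input("`table` must be a matrix with at least 2 rows and 2 columns.")
  }
  if (any(table < 0) || any(table != round(table))) {
    abort_bad_input("Counts must be non-negative integers.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort_degenerate("Contingency table has a zero row or column margin.")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value
  )
}
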