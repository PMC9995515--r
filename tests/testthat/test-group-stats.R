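test_that("Kruskal-Wallis matches the rank-definition brute force", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  d <- tibble::tibble(v = unlist(groups), g = rep(letters[1:3], each = 2))
  res <- kruskal_wallis(d, v, g)
  expect_equal(res$statistic, kw_brute_force(groups), tolerance = 1e-12)
  expect_equal(round(res$statistic, 3), 4.571)
  expect_equal(res$df, 2)

  # tied data still agree with the tie-corrected brute force
  set.seed(21)
  tied <- list(sample(1:4, 8, TRUE), sample(1:4, 6, TRUE), sample(1:4, 7, TRUE))
  dt <- tibble::tibble(v = unlist(tied), g = rep(letters[1:3], lengths(tied)))
  expect_equal(kruskal_wallis(dt, v, g)$statistic, kw_brute_force(tied), tolerance = 1e-12)

  same <- tibble::tibble(v = rep(5, 9), g = rep(letters[1:3], each = 3))
  res0 <- kruskal_wallis(same, v, g)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  expect_error(
    kruskal_wallis(tibble::tibble(v = 1:3, g = "a"), v, g),
    class = "resteeg_error_invalid_input"
  )
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed step-up", {
  expect_equal(fdr_adjust(0.031), 0.031)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_adjust(rep(0.2, 6)), rep(0.2, 6))

  set.seed(22)
  p <- runif(50)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # order-preserving in the raw p ranks
  expect_true(all(diff(adj[order(p)]) >= 0))

  expect_error(fdr_adjust(c(0.1, 1.2)), class = "resteeg_error_invalid_input")
  expect_error(fdr_adjust(c(-0.1)), class = "resteeg_error_invalid_input")
})

test_that("Tukey HSD agrees with stats::TukeyHSD and behaves at the extremes", {
  set.seed(23)
  d <- tibble::tibble(
    v = c(rnorm(8), rnorm(11, 0.4), rnorm(6, 1.5)),
    g = rep(c("a", "b", "c"), c(8, 11, 6))
  )
  mine <- posthoc_tukey(d, v, g)
  ref <- stats::TukeyHSD(stats::aov(v ~ g, data = d))$g
  expect_equal(mine$diff, unname(ref[, "diff"]), tolerance = 1e-12)
  expect_equal(mine$p_adj, unname(ref[, "p adj"]), tolerance = 1e-10)

  twin <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_gt(posthoc_tukey(twin, v, g)$p_adj, 0.99)

  far <- tibble::tibble(
    v = c(rnorm(10, 0, 0.1), rnorm(10, 50, 0.1), rnorm(10, 100, 0.1)),
    g = rep(c("a", "b", "c"), each = 10)
  )
  expect_true(all(posthoc_tukey(far, v, g)$p_adj < 0.001))

  flat <- tibble::tibble(v = rep(c(1, 2), each = 4), g = rep(c("a", "b"), each = 4))
  expect_error(posthoc_tukey(flat, v, g), class = "resteeg_error_degenerate")

  dunn <- posthoc_tukey(d, v, g, method = "dunn")
  expect_equal(nrow(dunn), 3)
  expect_true(all(dunn$p_adj >= 0 & dunn$p_adj <= 1))
})

test_that("summary-statistic t-test equals the raw-data pooled t-test", {
  set.seed(24)
  x <- rnorm(14, 3, 2)
  y <- rnorm(9, 4.2, 2.4)
  res <- t_test_from_summary(mean(x), sd(x), 14, mean(y), sd(y), 9)
  ref <- stats::t.test(y, x, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(ref$parameter))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  eq <- t_test_from_summary(5, 1, 10, 5, 2, 12)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  expect_error(t_test_from_summary(1, 1, 1, 2, 1, 5), class = "resteeg_error_invalid_input")
  expect_error(t_test_from_summary(1, 0, 5, 2, 0, 5), class = "resteeg_error_degenerate")
})

test_that("summary-statistic ANOVA equals aov and squares the pooled t for two groups", {
  set.seed(25)
  groups <- list(rnorm(12, 0), rnorm(15, 0.5), rnorm(9, 1))
  means <- vapply(groups, mean, 0)
  sds <- vapply(groups, sd, 0)
  ns <- lengths(groups)
  res <- anova_from_summary(means, sds, ns)
  d <- data.frame(v = unlist(groups), g = rep(letters[1:3], ns))
  ref <- summary(stats::aov(v ~ g, data = d))[[1]]
  expect_equal(res$statistic, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, sum(ns) - 3)
  expect_equal(res$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)

  t2 <- t_test_from_summary(means[1], sds[1], ns[1], means[2], sds[2], ns[2])
  f2 <- anova_from_summary(means[1:2], sds[1:2], ns[1:2])
  expect_equal(f2$statistic, t2$statistic^2, tolerance = 1e-10)

  flatf <- anova_from_summary(c(3, 3, 3), c(1, 2, 1), c(5, 5, 5))
  expect_equal(flatf$statistic, 0)

  expect_error(anova_from_summary(c(1, 2), c(0, 0), c(5, 5)), class = "resteeg_error_degenerate")
  expect_error(anova_from_summary(1, 1, 5), class = "resteeg_error_invalid_input")
})

test_that("Mann-Whitney U reports min(U1, U2) with exact enumeration p for small samples", {
  d <- tibble::tibble(v = c(1, 2, 3, 4), g = rep(c("a", "b"), each = 2))
  res <- mann_whitney_u(d, v, g)
  expect_equal(res$statistic, 0)

  sym <- tibble::tibble(v = rep(c(5, 7, 9), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(mann_whitney_u(sym, v, g)$statistic, 9 / 2)

  x <- c(1.1, 3.2, 5.5, 7.1)
  y <- c(2.0, 4.4, 6.3, 8.9, 9.9)
  d2 <- tibble::tibble(v = c(x, y), g = rep(c("a", "b"), c(4, 5)))
  res2 <- mann_whitney_u(d2, v, g)
  expect_true(res2$exact)
  expect_equal(res2$p_value, mw_enumerate_p(x, y), tolerance = 1e-12)

  # another configuration, closer to complete separation
  x3 <- c(0.3, 0.9, 1.4)
  y3 <- c(1.8, 2.6, 3.1, 4.4)
  d3 <- tibble::tibble(v = c(x3, y3), g = rep(c("a", "b"), c(3, 4)))
  expect_equal(mann_whitney_u(d3, v, g)$p_value, mw_enumerate_p(x3, y3), tolerance = 1e-12)

  tied <- tibble::tibble(v = c(1, 1, 2, 2, 3, 3, 4), g = rep(c("a", "b"), c(3, 4)))
  rt <- mann_whitney_u(tied, v, g)
  expect_false(rt$exact)
  expect_true(rt$p_value > 0 && rt$p_value <= 1)

  expect_error(
    mann_whitney_u(tibble::tibble(v = 1:3, g = c("a", "a", "a")), v, g),
    class = "resteeg_error_invalid_input"
  )
})

test_that("chi-squared matches the direct sum over (O-E)^2/E", {
  even <- matrix(c(10, 20, 10, 20), 2)
  expect_equal(chi_squared_contingency(even)$statistic, 0, tolerance = 1e-12)

  set.seed(26)
  tab <- matrix(rpois(15, 12) + 1, nrow = 5, ncol = 3)
  res <- chi_squared_contingency(tab)
  expect_equal(res$df, 8)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)

  zero <- matrix(c(3, 0, 5, 0), 2)
  expect_error(chi_squared_contingency(zero), class = "resteeg_error_degenerate")
  expect_error(chi_squared_contingency(matrix(1:3, 1)), class = "resteeg_error_invalid_input")
})

test_that("bootstrap correlation is deterministic, floored and exact for perfect association", {
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5, 6), y = c(1, 2, 3, 4, 5, 6))
  res <- tidy(pearson_bootstrap(d, x, y, B = 1000, seed = 1))
  expect_equal(res$r, 1)
  expect_equal(res$ci_low, 1)
  expect_equal(res$ci_high, 1)
  expect_equal(res$p_boot, 2 / 1000)

  set.seed(27)
  d2 <- tibble::tibble(x = rnorm(40), y = rnorm(40))
  a <- pearson_bootstrap(d2, x, y, B = 1500, seed = 99)
  b <- pearson_bootstrap(d2, x, y, B = 1500, seed = 99)
  expect_identical(tidy(a), tidy(b))
  c <- pearson_bootstrap(d2, x, y, B = 1500, seed = 100)
  expect_false(identical(tidy(a)$ci_low, tidy(c)$ci_low))

  # missing entries are dropped pairwise
  d3 <- d2
  d3$x[1:5] <- NA
  expect_equal(tidy(pearson_bootstrap(d3, x, y, B = 1000, seed = 1))$n, 35)

  expect_error(
    pearson_bootstrap(tibble::tibble(x = 1:2, y = 2:3), x, y, B = 1000),
    class = "resteeg_error_invalid_input"
  )
  expect_error(pearson_bootstrap(d2, x, y, B = 50), class = "resteeg_error_invalid_input")
  expect_error(
    pearson_bootstrap(tibble::tibble(x = rep(1, 10), y = rnorm(10)), x, y, B = 1000),
    class = "resteeg_error_degenerate"
  )
})

test_that("channel-wise analysis controls the family and reports directions", {
  set.seed(28)
  n <- 12
  units <- sprintf("ch%02d", 1:6)
  d <- tidyr::expand_grid(unit = units, group = c("never", "past", "smoker"),
    idx = seq_len(n))
  d$value <- rnorm(nrow(d))
  # plant a large effect in ch03 only: smoker below the others
  d$value[d$unit == "ch03" & d$group == "smoker"] <-
    d$value[d$unit == "ch03" & d$group == "smoker"] - 4

  rep_ <- channelwise_group_analysis(d, value, group, unit, family = "demo")
  om <- tidy(rep_)
  expect_equal(nrow(om), 6)
  expect_true(all(om$p_fdr >= om$p_value))
  expect_true(om$significant[om$unit == "ch03"])
  expect_equal(sum(om$significant), 1)

  ph <- posthoc_results(rep_)
  expect_true(all(ph$unit == "ch03"))
  sn <- ph[ph$group_a == "smoker" & ph$group_b == "never", ]
  expect_lt(sn$p_adj, 0.01)
  expect_equal(sn$direction, -1)

  expect_equal(glance(rep_)$n_significant, 1)

  small <- d[d$idx <= 2, ]
  expect_error(
    channelwise_group_analysis(small, value, group, unit),
    class = "resteeg_error_degenerate"
  )
})
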