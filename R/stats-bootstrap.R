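# Bootstrap Pearson correlation.

#' Pearson correlation with nonparametric bootstrap inference
#'
#' Computes the Pearson correlation on pairwise-complete observations and
#' draws `B` paired resamples with replacement to form a percentile
#' confidence interval and a two-sided bootstrap p-value, defined as twice
#' the smaller of the fractions of resampled correlations at or below /
#' at or above zero, floored at `2/B`. Resamples with zero variance in
#' either variable (possible with heavily tied data) are dropped from the
#' percentile computations. The result is a deterministic function of
#' (data, B, seed).
#'
#' @param data Data frame holding the two variables.
#' @param x,y Columns to correlate (tidy-eval). Missing entries are
#'   removed pairwise.
#' @param B Number of bootstrap resamples (at least 1000; default 10000).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level of the percentile interval.
#' @return An `eeg_correlation` object; use [tidy()] for a one-row
#'   tibble with `r`, `ci_low`, `ci_high`, `p_boot`, `n`, `B`.
#' @export
pearson_bootstrap <- function(data, x, y, B = 10000, seed = NULL, conf = 0.95) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  n <- length(xv)
  if (n < 3) abort_bad_input("Need at least 3 pairwise-complete observations.")
  if (B < 1000) abort_bad_input("`B` must be at least 1000.")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    abort_degenerate("Zero variance in x or y; correlation undefined.")
  }
  r_hat <- stats::cor(xv, yv)

  boot_r <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    xm <- matrix(xv[idx], nrow = B)
    ym <- matrix(yv[idx], nrow = B)
    mx <- rowMeans(xm)
    my <- rowMeans(ym)
    sxy <- rowMeans(xm * ym) - mx * my
    sxx <- rowMeans(xm * xm) - mx^2
    syy <- rowMeans(ym * ym) - my^2
    r <- sxy / sqrt(sxx * syy)
    r[is.finite(r)]
  })
  alpha2 <- (1 - conf) / 2
  ci <- stats::quantile(boot_r, c(alpha2, 1 - alpha2), names = FALSE)
  p <- 2 * min(mean(boot_r <= 0), mean(boot_r >= 0))
  p <- min(1, max(p, 2 / B))
  structure(
    list(
      r = r_hat, n = n, B = B, seed = seed, conf = conf,
      ci_low = ci[1], ci_high = ci[2], p_boot = p,
      x = rlang::as_name(rlang::enquo(x)),
      y = rlang::as_name(rlang::enquo(y))
    ),
    class = "eeg_correlation"
  )
}

#' @export
print.eeg_correlation <- function(x, ...) {
  cat(sprintf(
    "<eeg_correlation> %s ~ %s: r = %.3f, %d%% CI [%.3f, %.3f], bootstrap p = %.4g (n = %d, B = %d)\n",
    x$x, x$y, x$r, round(100 * x$conf), x$ci_low, x$ci_high, x$p_boot, x$n, x$B
  ))
  invisible(x)
}

#' @method tidy eeg_correlation
#' @export
tidy.eeg_correlation <- function(x, ...) {
  tibble::tibble(
    feature = x$x, covariate = x$y, n = x$n, r = x$r,
    ci_low = x$ci_low, ci_high = x$ci_high, p_boot = x$p_boot, B = x$B
  )
}

#' @method glance eeg_correlation
#' @export
glance.eeg_correlation <- function(x, ...) {
  tibble::tibble(r = x$r, p_boot = x$p_boot, n = x$n, B = x$B, conf = x$conf)
}
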