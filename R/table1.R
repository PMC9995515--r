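# Recompute demographic-table test statistics from printed summaries.

#' Validate a printed demographic summary table
#'
#' Reads a plain-text transcription of a published demographics table
#' (per-measure, per-group mean, SD and n, plus the printed statistic) and
#' recomputes every two-sample pooled t statistic and one-way F statistic
#' from those summaries with [t_test_from_summary()] and
#' [anova_from_summary()]. Statistics are compared on their absolute value,
#' since the sign of a printed t depends on the group ordering convention.
#'
#' The file must be a CSV with columns `measure`, `test` (`"t"` or
#' `"anova"`), `order` (group position within the measure), `group`,
#' `mean`, `sd`, `n`, `printed_statistic`, `printed_df1` and optionally
#' `printed_df2`. A transcription of the study's Table 1 ships with the
#' package: `system.file("extdata", "table1_summary.csv", package =
#' "resteeg")`.
#'
#' @param path Path to the summary CSV.
#' @param tolerance Allowed absolute difference between recomputed and
#'   printed statistics; the default 0.02 reflects rounding of the printed
#'   two-decimal inputs.
#' @return A tibble with one row per measure: recomputed statistic and
#'   degrees of freedom, printed values, `abs_diff` and a logical `match`.
#' @export
validate_table1 <- function(path, tolerance = 0.02) {
  if (!file.exists(path)) abort_io(sprintf("Summary file '%s' not found.", path))
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(
      measure = readr::col_character(),
      test = readr::col_character(),
      group = readr::col_character(),
      .default = readr::col_double()
    )
  )
  need <- c("measure", "test", "order", "group", "mean", "sd", "n",
    "printed_statistic", "printed_df1")
  if (!all(need %in% names(tab))) {
    abort_bad_input(paste(
      "Summary file must have columns", paste(need, collapse = ", ")
    ))
  }
  rows <- list()
  for (m in unique(tab$measure)) {
    sub <- dplyr::arrange(tab[tab$measure == m, ], .data$order)
    if (any(is.na(sub$mean)) || any(is.na(sub$sd)) || any(is.na(sub$n))) {
      abort_bad_input(sprintf("Malformed row(s) for measure '%s': missing mean/sd/n.", m))
    }
    kind <- sub$test[1]
    if (kind == "t") {
      if (nrow(sub) != 2) {
        abort_bad_input(sprintf("Measure '%s': a t-test needs exactly 2 group rows.", m))
      }
      res <- t_test_from_summary(
        sub$mean[1], sub$sd[1], sub$n[1],
        sub$mean[2], sub$sd[2], sub$n[2]
      )
      rows[[m]] <- tibble::tibble(
        measure = m, test = "t",
        statistic = res$statistic, df1 = res$df, df2 = NA_real_,
        p_value = res$p_value,
        printed_statistic = sub$printed_statistic[1],
        printed_df1 = sub$printed_df1[1],
        printed_df2 = NA_real_
      )
    } else if (kind == "anova") {
      if (nrow(sub) < 2) {
        abort_bad_input(sprintf("Measure '%s': ANOVA needs at least 2 group rows.", m))
      }
      res <- anova_from_summary(sub$mean, sub$sd, sub$n)
      rows[[m]] <- tibble::tibble(
        measure = m, test = "anova",
        statistic = res$statistic, df1 = res$df1, df2 = res$df2,
        p_value = res$p_value,
        printed_statistic = sub$printed_statistic[1],
        printed_df1 = sub$printed_df1[1],
        printed_df2 = sub$printed_df2[1] %||% NA_real_
      )
    } else {
      abort_bad_input(sprintf("Measure '%s': unknown test kind '%s'.", m, kind))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$abs_diff <- abs(abs(out$statistic) - abs(out$printed_statistic))
  out$match <- out$abs_diff <= tolerance
  out
}
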