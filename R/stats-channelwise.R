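# Channel-wise (or channel-pair-wise) group analysis with FDR control.

#' Channel-wise group comparison with FDR control
#'
#' Runs one Kruskal-Wallis omnibus test per analysis unit (channel, or
#' channel pair for coherence), adjusts the resulting p-values with the
#' Benjamini-Hochberg procedure within the family (one feature by band by
#' condition; 31 channels or 465 pairs), and computes post-hoc pairwise
#' comparisons (Tukey HSD by default) only for units whose omnibus test
#' survives FDR at `alpha`.
#'
#' @param data One row per subject and unit, with value, group and unit
#'   columns.
#' @param value,group,unit Columns (tidy-eval): feature value, group
#'   label, analysis unit.
#' @param alpha Significance level applied to FDR-adjusted p-values.
#' @param posthoc `"tukey"` or `"dunn"`.
#' @param family Optional family label stored in the report.
#' @return An `eeg_group_report` with elements `omnibus` (tibble: `unit`,
#'   `n`, `statistic`, `df`, `p_value`, `p_fdr`, `significant`) and
#'   `posthoc` (tibble: `unit`, `group_a`, `group_b`, `diff`, `p_adj`,
#'   `direction`).
#' @export
channelwise_group_analysis <- function(data, value, group, unit,
                                       alpha = 0.05,
                                       posthoc = c("tukey", "dunn"),
                                       family = NULL) {
  posthoc <- match.arg(posthoc)
  df <- dplyr::tibble(
    value = dplyr::pull(data, {{ value }}),
    group = as.character(dplyr::pull(data, {{ group }})),
    unit = dplyr::pull(data, {{ unit }})
  )
  df <- dplyr::filter(df, is.finite(.data$value))
  counts <- df |>
    dplyr::count(.data$unit, .data$group) |>
    dplyr::group_by(.data$unit) |>
    dplyr::summarise(k = dplyr::n(), min_n = min(.data$n), .groups = "drop")
  if (any(counts$k < 2) || any(counts$min_n < 3)) {
    abort_degenerate("Every unit needs at least 2 groups with at least 3 subjects each.")
  }

  gf <- factor(df$group)
  idx_by_unit <- split(seq_len(nrow(df)), df$unit)
  stats3 <- vapply(idx_by_unit, function(ix) {
    v <- df$value[ix]
    g <- gf[ix]
    if (length(unique(v)) == 1) {
      c(0, nlevels(droplevels(g)) - 1, 1)
    } else {
      kt <- stats::kruskal.test(v, g)
      c(unname(kt$statistic), unname(kt$parameter), kt$p.value)
    }
  }, numeric(3))
  omnibus <- tibble::tibble(
    unit = names(idx_by_unit),
    n = lengths(idx_by_unit),
    statistic = stats3[1, ],
    df = stats3[2, ],
    p_value = stats3[3, ]
  )
  omnibus$p_fdr <- fdr_adjust(omnibus$p_value)
  omnibus$significant <- omnibus$p_fdr < alpha

  ph <- omnibus$unit[omnibus$significant]
  posthoc_tbl <- if (length(ph)) {
    parts <- lapply(ph, function(u) {
      ix <- idx_by_unit[[u]]
      res <- if (posthoc == "tukey") {
        tukey_hsd(df$value[ix], droplevels(gf[ix]))
      } else {
        dunn_test(df$value[ix], droplevels(gf[ix]))
      }
      res$unit <- u
      res
    })
    dplyr::relocate(dplyr::bind_rows(parts), "unit")
  } else {
    tibble::tibble(
      unit = character(), group_a = character(), group_b = character(),
      diff = double(), p_adj = double(), direction = double()
    )
  }

  structure(
    list(
      omnibus = omnibus, posthoc = posthoc_tbl,
      alpha = alpha, family = family %||% NA_character_, posthoc_method = posthoc
    ),
    class = "eeg_group_report"
  )
}

#' @export
print.eeg_group_report <- function(x, ...) {
  cat(sprintf(
    "<eeg_group_report> family '%s': %d units, %d significant at FDR %.2g (post hoc: %s)\n",
    x$family, nrow(x$omnibus), sum(x$omnibus$significant), x$alpha, x$posthoc_method
  ))
  invisible(x)
}

#' @method tidy eeg_group_report
#' @export
tidy.eeg_group_report <- function(x, ...) {
  dplyr::mutate(x$omnibus, family = x$family, .before = 1)
}

#' @method glance eeg_group_report
#' @export
glance.eeg_group_report <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n_units = nrow(x$omnibus),
    n_significant = sum(x$omnibus$significant),
    alpha = x$alpha,
    posthoc = x$posthoc_method
  )
}

#' Post-hoc pairwise results of a group report
#' @param report An `eeg_group_report`.
#' @return Tibble of pairwise comparisons for FDR-significant units.
#' @export
posthoc_results <- function(report) {
  stopifnot(inherits(report, "eeg_group_report"))
  report$posthoc
}
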