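# ggplot2 visualizations for the main result types.

#' Plot relative band powers by group
#'
#' Boxplots of per-subject channel-averaged relative band power, split by
#' group and faceted by condition.
#'
#' @param features Feature table (columns `subject`, `group`, `condition`,
#'   `channel`, `band`, `rel_power`).
#' @return A ggplot object.
#' @export
plot_band_powers <- function(features) {
  dat <- features |>
    dplyr::group_by(.data$subject, .data$group, .data$condition, .data$band) |>
    dplyr::summarise(rel_power = mean(.data$rel_power), .groups = "drop") |>
    dplyr::mutate(band = factor(.data$band, levels = eeg_bands()$band))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$band, y = .data$rel_power, fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(
      x = NULL, y = "relative band power",
      title = "Channel-averaged relative band power"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot eeg_group_report
#' @export
autoplot.eeg_group_report <- function(object, ...) {
  dat <- dplyr::mutate(object$omnibus, unit = factor(.data$unit, levels = .data$unit))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$unit, y = -log10(.data$p_fdr))) +
    ggplot2::geom_point(ggplot2::aes(color = .data$significant), size = 1.5) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = expression(-log[10] ~ italic(P)[FDR]),
      title = sprintf("Channel-wise group test: %s", object$family)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}

#' @method autoplot eeg_coherence_matrix
#' @export
autoplot.eeg_coherence_matrix <- function(object, ...) {
  channels <- attr(object, "channels")
  dat <- tibble::tibble(
    ch_a = factor(rep(channels, times = length(channels)), levels = channels),
    ch_b = factor(rep(channels, each = length(channels)), levels = rev(channels)),
    coherence = as.vector(unclass(object))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ch_a, y = .data$ch_b, fill = .data$coherence)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("%s band coherence", attr(object, "band"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6),
      axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot bootstrap feature-covariate correlations
#'
#' Point estimates with percentile confidence intervals for each
#' feature-covariate pair.
#'
#' @param correlations Tidy correlation table (from an
#'   [analyze_cohort()] result).
#' @return A ggplot object.
#' @export
plot_correlations <- function(correlations) {
  dat <- dplyr::mutate(correlations,
    pair = paste(.data$feature, .data$covariate, sep = " ~ ")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$r, y = .data$pair)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Pearson r (bootstrap 95% CI)", y = NULL,
      title = "EEG feature vs covariate correlations"
    ) +
    ggplot2::theme_minimal()
}
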