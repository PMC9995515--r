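# End-to-end orchestration: generate/load -> preprocess -> features ->
# coherence -> statistics, streamed subject by subject.

# Run preprocessing + feature extraction for every subject x condition of a
# synthetic cohort without materializing all recordings at once.
cohort_feature_tables <- function(config, low = 1, high = 50, car = TRUE,
                                  epoch_length = 2, amp_threshold = 75,
                                  bands = eeg_bands()) {
  subjects <- cohort_subjects(config)
  feats <- list()
  cohs <- list()
  exclusions <- list()
  k <- 0L
  for (i in seq_len(nrow(subjects))) {
    for (cond in c("EC", "EO")) {
      rec <- generate_recording(
        group = subjects$group[i], condition = cond, config = config,
        subject_seed = subjects$subject_seed[i], subject_id = subjects$subject[i]
      )
      ep <- preprocess_recording(
        rec,
        low = low, high = high, car = car,
        epoch_length = epoch_length, amp_threshold = amp_threshold
      )
      if (is_excluded(ep) || sum(ep$retained) < 2) {
        exclusions[[length(exclusions) + 1L]] <- tibble::tibble(
          subject = subjects$subject[i], group = subjects$group[i],
          condition = cond, reason = "amplitude_rejection",
          n_epochs_retained = sum(ep$retained)
        )
        next
      }
      k <- k + 1L
      feats[[k]] <- subject_band_powers(ep, bands)
      feats[[k]]$n_epochs <- attr(feats[[k]], "n_epochs")
      cohs[[k]] <- subject_band_coherence(ep, bands)
    }
  }
  list(
    features = dplyr::bind_rows(feats),
    coherence = dplyr::bind_rows(cohs),
    exclusions = if (length(exclusions)) dplyr::bind_rows(exclusions) else
      tibble::tibble(
        subject = character(), group = character(), condition = character(),
        reason = character(), n_epochs_retained = integer()
      )
  )
}

# Reactivity per subject x channel x band from the epoch-averaged band
# powers of both conditions ("absolute"), or from relative powers.
reactivity_table <- function(features, source = c("absolute", "relative")) {
  source <- match.arg(source)
  col <- if (source == "absolute") "abs_power" else "rel_power"
  wide <- features |>
    dplyr::select("subject", "group", "condition", "channel", "band",
      power = dplyr::all_of(col)
    ) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "power")
  if (!all(c("EC", "EO") %in% names(wide))) {
    return(tibble::tibble(
      subject = character(), group = character(), channel = character(),
      band = character(), reactivity = double()
    ))
  }
  wide |>
    dplyr::filter(is.finite(.data$EC), is.finite(.data$EO), .data$EC > 0) |>
    dplyr::mutate(reactivity = (.data$EC - .data$EO) / .data$EC) |>
    dplyr::select("subject", "group", "channel", "band", "reactivity")
}

# Channel-averaged subject-level summary used for covariate planting and
# feature-covariate correlations.
summarise_subject_features <- function(tables, inclusion = NULL,
                                       reactivity_source = "absolute") {
  features <- tables$features
  coherence <- tables$coherence
  if (!is.null(inclusion)) {
    ok <- inclusion[inclusion$included, c("subject", "condition")]
    features <- dplyr::semi_join(features, ok, by = c("subject", "condition"))
    coherence <- dplyr::semi_join(coherence, ok, by = c("subject", "condition"))
  }
  rel <- features |>
    dplyr::group_by(.data$subject, .data$group, .data$condition, .data$band) |>
    dplyr::summarise(value = mean(.data$rel_power), .groups = "drop") |>
    dplyr::mutate(
      name = paste0("rel_", .data$band, "_", tolower(.data$condition))
    ) |>
    dplyr::select("subject", "group", "name", "value")
  reac <- reactivity_table(features, source = reactivity_source) |>
    dplyr::group_by(.data$subject, .data$group, .data$band) |>
    dplyr::summarise(value = mean(.data$reactivity), .groups = "drop") |>
    dplyr::mutate(name = paste0(.data$band, "_reactivity")) |>
    dplyr::select("subject", "group", "name", "value")
  coh <- coherence |>
    dplyr::group_by(.data$subject, .data$group, .data$condition, .data$band) |>
    dplyr::summarise(value = mean(.data$coherence), .groups = "drop") |>
    dplyr::mutate(
      name = paste0(.data$band, "_coherence_", tolower(.data$condition))
    ) |>
    dplyr::select("subject", "group", "name", "value")
  # the per-band coherence summary equals the lower-triangle mean: the tidy
  # pair table holds exactly the strictly-below-diagonal entries
  dplyr::bind_rows(rel, reac, coh) |>
    tidyr::pivot_wider(names_from = "name", values_from = "value")
}

#' Analyze a synthetic cohort end to end
#'
#' Runs the full analysis graph on a configured synthetic cohort:
#' per-subject preprocessing (1-50 Hz band-pass, common average reference,
#' two-second epochs, 75 microvolt amplitude rejection), spectral band
#' powers, eyes-closed/eyes-open reactivity, pairwise band coherence, the
#' per-condition spectral-power outlier screen, channel-wise Kruskal-Wallis
#' tests with Benjamini-Hochberg FDR and Tukey post hocs, and bootstrap
#' feature-covariate correlations across the two smoker groups.
#'
#' @param config An [effect_config()].
#' @param alpha Significance level for FDR-adjusted p-values.
#' @param sd_threshold SD multiple of the power-outlier screen.
#' @param amp_threshold Amplitude rejection threshold (microvolts).
#' @param epoch_length Epoch length in seconds.
#' @param car Apply common average reference?
#' @param reactivity_source `"absolute"` (epoch-averaged absolute band
#'   power, the default) or `"relative"`.
#' @param bootstrap_B Bootstrap resamples for correlations.
#' @param posthoc `"tukey"` or `"dunn"`.
#' @param correlation_groups Groups across which feature-covariate
#'   correlations are evaluated.
#' @return An `eeg_cohort_analysis` list: `features`, `reactivity`,
#'   `coherence`, `inclusion`, `summary`, `covariates`, `reports` (named
#'   list of [channelwise_group_analysis()] results), `correlations`,
#'   `exclusions`, and the `config`.
#' @export
analyze_cohort <- function(config, alpha = 0.05, sd_threshold = 3,
                           amp_threshold = 75, epoch_length = 2, car = TRUE,
                           reactivity_source = c("absolute", "relative"),
                           bootstrap_B = 2000,
                           posthoc = c("tukey", "dunn"),
                           correlation_groups = c("past", "smoker")) {
  stopifnot(inherits(config, "effect_config"))
  reactivity_source <- match.arg(reactivity_source)
  posthoc <- match.arg(posthoc)

  tables <- cohort_feature_tables(
    config,
    car = car, epoch_length = epoch_length, amp_threshold = amp_threshold
  )
  inclusion <- exclude_power_outliers(tables$features, sd_threshold = sd_threshold)
  excl_outlier <- inclusion |>
    dplyr::filter(!.data$included) |>
    dplyr::transmute(
      .data$subject, .data$group, .data$condition,
      reason = "power_outlier", n_epochs_retained = NA_integer_
    )
  exclusions <- dplyr::bind_rows(tables$exclusions, excl_outlier)

  ok <- inclusion[inclusion$included, c("subject", "condition")]
  features_inc <- dplyr::semi_join(tables$features, ok, by = c("subject", "condition"))
  coherence_inc <- dplyr::semi_join(tables$coherence, ok, by = c("subject", "condition"))
  reactivity <- reactivity_table(features_inc, source = reactivity_source)

  summary_tbl <- summarise_subject_features(
    tables,
    inclusion = inclusion, reactivity_source = reactivity_source
  )
  covariates <- generate_covariates(config, features = summary_tbl)

  bands <- eeg_bands()$band
  reports <- list()
  for (b in bands) {
    for (cond in c("EC", "EO")) {
      fam <- sprintf("rel_power_%s_%s", b, tolower(cond))
      dat <- dplyr::filter(features_inc, .data$band == b, .data$condition == cond)
      reports[[fam]] <- channelwise_group_analysis(
        dat, rel_power, group, channel,
        alpha = alpha, posthoc = posthoc, family = fam
      )
    }
    fam <- sprintf("reactivity_%s", b)
    dat <- dplyr::filter(reactivity, .data$band == b)
    if (nrow(dat)) {
      reports[[fam]] <- channelwise_group_analysis(
        dat, reactivity, group, channel,
        alpha = alpha, posthoc = posthoc, family = fam
      )
    }
    for (cond in c("EC", "EO")) {
      fam <- sprintf("coherence_%s_%s", b, tolower(cond))
      dat <- dplyr::filter(coherence_inc, .data$band == b, .data$condition == cond) |>
        dplyr::mutate(pair = paste(.data$ch_a, .data$ch_b, sep = "-"))
      reports[[fam]] <- channelwise_group_analysis(
        dat, coherence, group, pair,
        alpha = alpha, posthoc = posthoc, family = fam
      )
    }
  }

  corr_features <- intersect(
    c("rel_theta_ec", "rel_alpha_ec", "alpha_reactivity", "alpha_coherence_ec"),
    names(summary_tbl)
  )
  corr_covariates <- intersect(
    c("cigarettes_per_day", "ftnd", "qsu", "quit_attempts", "years_smoking"),
    names(covariates)
  )
  corr_data <- summary_tbl |>
    dplyr::inner_join(covariates, by = c("subject", "group")) |>
    dplyr::filter(.data$group %in% correlation_groups)
  correlations <- list()
  for (f in corr_features) {
    for (cv in corr_covariates) {
      res <- tryCatch(
        pearson_bootstrap(
          corr_data,
          x = !!rlang::sym(f), y = !!rlang::sym(cv),
          B = bootstrap_B, seed = child_seed(config$seed, 2L, stream = 11L)
        ),
        resteeg_error_invalid_input = function(e) NULL,
        resteeg_error_degenerate = function(e) NULL
      )
      if (!is.null(res)) correlations[[paste(f, cv, sep = "~")]] <- tidy(res)
    }
  }
  correlations <- dplyr::bind_rows(correlations)

  structure(
    list(
      features = tables$features,
      reactivity = reactivity,
      coherence = tables$coherence,
      inclusion = inclusion,
      summary = summary_tbl,
      covariates = covariates,
      reports = reports,
      correlations = correlations,
      exclusions = exclusions,
      config = config
    ),
    class = "eeg_cohort_analysis"
  )
}

#' @export
print.eeg_cohort_analysis <- function(x, ...) {
  cat("<eeg_cohort_analysis>\n")
  cat(sprintf(
    "  %d subjects, %d families tested, %d subject x condition exclusions\n",
    length(unique(x$features$subject)), length(x$reports), nrow(x$exclusions)
  ))
  sig <- purrr::map_int(x$reports, ~ sum(.x$omnibus$significant))
  sig <- sig[sig > 0]
  if (length(sig)) {
    cat("  significant families:\n")
    for (nm in names(sig)) cat(sprintf("    %s: %d units\n", nm, sig[[nm]]))
  } else {
    cat("  no FDR-significant units\n")
  }
  invisible(x)
}

#' @method glance eeg_cohort_analysis
#' @export
glance.eeg_cohort_analysis <- function(x, ...) {
  purrr::map_dfr(x$reports, glance)
}

#' Run the pipeline and write its outputs to a directory
#'
#' Executes [analyze_cohort()] and serializes every result as tidy CSV
#' (feature tables, reactivity, coherence pairs, covariates, inclusion
#' mask, omnibus and post-hoc group tests, correlations, exclusion log),
#' together with a machine-readable JSON summary embedding a hash of the
#' configuration, and a plain-text run log. Running twice with the same
#' configuration produces byte-identical outputs.
#'
#' @param config An [effect_config()].
#' @param out_dir Output directory; created if absent. Must be empty
#'   unless `overwrite = TRUE`.
#' @param overwrite Allow writing into a non-empty directory?
#' @param ... Passed to [analyze_cohort()].
#' @return The `eeg_cohort_analysis`, invisibly; outputs on disk.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE, ...) {
  if (!inherits(config, "effect_config")) {
    abort_bad_input("`config` must be an effect_config object.")
  }
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    abort_bad_input(sprintf("Output directory '%s' is not empty.", out_dir))
  }
  res <- analyze_cohort(config, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  readr::write_csv(res$features, file.path(out_dir, "features.csv"))
  readr::write_csv(res$reactivity, file.path(out_dir, "reactivity.csv"))
  readr::write_csv(res$coherence, file.path(out_dir, "coherence_pairs.csv"))
  readr::write_csv(res$inclusion, file.path(out_dir, "inclusion.csv"))
  readr::write_csv(res$summary, file.path(out_dir, "subject_summary.csv"))
  readr::write_csv(res$covariates, file.path(out_dir, "covariates.csv"))
  readr::write_csv(res$correlations, file.path(out_dir, "correlations.csv"))
  readr::write_csv(res$exclusions, file.path(out_dir, "exclusions.csv"))
  omnibus <- purrr::map_dfr(res$reports, tidy)
  posthoc <- purrr::map_dfr(res$reports, function(r) {
    dplyr::mutate(r$posthoc, family = r$family, .before = 1)
  })
  readr::write_csv(omnibus, file.path(out_dir, "group_tests.csv"))
  readr::write_csv(posthoc, file.path(out_dir, "posthoc.csv"))
  write_effect_config(config, file.path(out_dir, "config.yaml"))

  summary_json <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    n_subjects = sum(config$n_per_group),
    n_families = length(res$reports),
    n_exclusions = nrow(res$exclusions),
    significant_units = lapply(res$reports, function(r) sum(r$omnibus$significant))
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  log_lines <- c(
    sprintf("resteeg run, config hash %s, seed %d", rlang::hash(config), config$seed),
    sprintf(
      "groups: %s",
      paste(sprintf("%s=%d", config$groups, config$n_per_group), collapse = ", ")
    ),
    sprintf(
      "exclusions: %s",
      if (nrow(res$exclusions)) {
        paste(sprintf(
          "%s/%s (%s)", res$exclusions$subject, res$exclusions$condition,
          res$exclusions$reason
        ), collapse = ", ")
      } else {
        "none"
      }
    )
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(res)
}
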