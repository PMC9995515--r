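# Whole-cohort generation.

#' Generate a full synthetic cohort
#'
#' Materializes two recordings (eyes-closed, eyes-open) for every subject
#' of every group, the covariate table, and the ground truth needed to
#' verify downstream recovery (per-subject seeds, realized band-amplitude
#' multipliers, shared-source polarities, injected artifacts). When
#' correlations are planted, the standard feature pipeline is run
#' internally so covariates can be blended with the realized features.
#'
#' Recordings at the full study scale (31 channels, 500 Hz, 180 s, 81
#' subjects, two conditions) occupy several gigabytes; for exploratory or
#' test use, configure a shorter `duration`/`sample_rate`, or use
#' [analyze_cohort()] which streams subjects without materializing the
#' whole cohort.
#'
#' @param config An [effect_config()].
#' @return A list with elements `recordings` (list of [eeg_recording()],
#'   EC and EO per subject), `covariates` (tibble) and `ground_truth`
#'   (list: `subjects` tibble with realized per-subject parameters, the
#'   `config`, and the master seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "effect_config"))
  subjects <- cohort_subjects(config)
  recordings <- vector("list", 2L * nrow(subjects))
  k <- 0L
  for (i in seq_len(nrow(subjects))) {
    for (cond in c("EC", "EO")) {
      k <- k + 1L
      recordings[[k]] <- generate_recording(
        group = subjects$group[i], condition = cond, config = config,
        subject_seed = subjects$subject_seed[i], subject_id = subjects$subject[i]
      )
    }
  }
  names(recordings) <- vapply(
    recordings, function(r) paste(r$subject_id, r$condition, sep = "_"), ""
  )

  features <- NULL
  if (nrow(config$planted_correlations)) {
    feats <- cohort_feature_tables(config)
    features <- summarise_subject_features(feats)
  }
  covariates <- generate_covariates(config, features = features)

  realized <- lapply(seq_len(nrow(subjects)), function(i) {
    p <- subject_params(config, subjects$group[i], subjects$subject_seed[i])
    tibble::tibble(
      subject = subjects$subject[i],
      band = names(p$band_mult),
      amplitude_multiplier = unname(p$band_mult)
    )
  })
  ground_truth <- list(
    subjects = subjects,
    band_multipliers = dplyr::bind_rows(realized),
    spikes = config$spikes,
    power_outliers = config$power_outliers,
    config = config,
    seed = config$seed
  )
  list(recordings = recordings, covariates = covariates, ground_truth = ground_truth)
}
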