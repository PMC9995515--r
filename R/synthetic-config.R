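# Configuration for the synthetic three-group EEG cohort generator.

#' Default 31-channel montage
#'
#' Standard 10-20/10-10 labels for a 31-electrode cap covering frontal,
#' central, temporal, parietal and occipital sites.
#'
#' @return Character vector of 31 channel labels.
#' @export
default_montage <- function() {
  c(
    "Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "FT9",
    "FC1", "FC2", "FC5", "FC6", "T7", "T8", "C3", "C4", "Cz",
    "TP9", "TP10", "CP1", "CP2", "CP5", "CP6",
    "P3", "P4", "P7", "P8", "Pz", "O1", "O2", "Oz"
  )
}

default_band_amplitude <- function() {
  tibble::tribble(
    ~band,    ~never, ~past, ~smoker,
    "delta",     5.0,   5.0,     5.0,
    "theta",     5.0,   4.2,     3.8,
    "alpha",     6.0,   6.0,     7.5,
    "beta",      3.0,   3.0,     3.0,
    "gamma",     1.5,   1.5,     1.5
  )
}

# Group means/SDs/bounds and missing rates for each covariate. Values mirror
# a matched three-group male cohort in its fifties; smoking measures exist
# only for the two smoker groups, and missingness rates reflect typical
# self-report completeness.
default_covariate_spec <- function() {
  tibble::tribble(
    ~covariate,           ~group,   ~mean,  ~sd,  ~lower, ~upper, ~missing_rate, ~integer,
    "age",                "never",  53.09, 4.96,      42,     70,             0,    FALSE,
    "age",                "past",   54.64, 6.48,      42,     70,             0,    FALSE,
    "age",                "smoker", 56.30, 7.12,      42,     70,             0,    FALSE,
    "education",          "never",   3.67, 1.14,       1,      5,             0,     TRUE,
    "education",          "past",    3.32, 1.12,       1,      5,             0,     TRUE,
    "education",          "smoker",  3.00, 0.97,       1,      5,             0,     TRUE,
    "income",             "never",   3.15, 1.25,       1,      6,             0,     TRUE,
    "income",             "past",    3.14, 1.41,       1,      6,             0,     TRUE,
    "income",             "smoker",  2.85, 1.42,       1,      6,             0,     TRUE,
    "kbdi",               "never",   8.63, 6.89,       0,     63,             0,    FALSE,
    "kbdi",               "past",    9.96, 6.50,       0,     63,             0,    FALSE,
    "kbdi",               "smoker",  8.75, 6.27,       0,     63,             0,    FALSE,
    "initiation_age",     "past",   19.43, 1.32,      14,     25,             0,    FALSE,
    "initiation_age",     "smoker", 18.10, 1.80,      14,     25,             0,    FALSE,
    "years_smoking",      "past",   10.21, 6.43,     0.5,     20,             0,    FALSE,
    "years_smoking",      "smoker", 37.80, 7.54,      20,     50,             0,    FALSE,
    "cigarettes_per_day", "past",   18.24, 9.05,       5,     60,          7/28,    FALSE,
    "cigarettes_per_day", "smoker", 20.53, 6.76,       5,     60,          1/20,    FALSE,
    "quit_attempts",      "past",    2.11, 2.11,       1,     10,         10/28,     TRUE,
    "quit_attempts",      "smoker",  2.15, 1.04,       1,     10,             0,     TRUE,
    "ftnd",               "past",    3.15, 3.17,       0,     10,          8/28,    FALSE,
    "ftnd",               "smoker",  5.58, 2.09,       0,     10,          1/20,    FALSE,
    "qsu",                "past",   10.80, 2.73,      10,     50,          8/28,    FALSE,
    "qsu",                "smoker", 21.32, 10.17,     10,     50,          1/20,    FALSE
  )
}

default_planted_correlations <- function() {
  tibble::tribble(
    ~covariate,           ~feature,            ~r,
    "cigarettes_per_day", "rel_theta_ec",       -0.31,
    "ftnd",               "rel_theta_ec",       -0.40,
    "quit_attempts",      "rel_theta_ec",        0.43,
    "cigarettes_per_day", "alpha_coherence_ec",  0.39
  )
}

#' Configure a synthetic EEG cohort
#'
#' Defines the ground truth of a three-group synthetic cohort. Each
#' channel's signal is a sum of band-limited Gaussian components (one per
#' frequency band, at configured RMS amplitudes) plus a 1/f background.
#' The eyes-closed condition multiplies the alpha amplitude by
#' `alpha_ec_gain`; a fraction `alpha_shared_fraction` of each channel's
#' alpha variance is driven by a single shared source (with
#' channel-specific polarity), which is what induces inter-channel alpha
#' coherence. Per-subject log-normal amplitude jitter creates individual
#' differences, shared between conditions.
#'
#' The defaults describe a cohort in which both smoker groups have reduced
#' theta amplitude relative to never-smokers, while only current smokers
#' have elevated alpha amplitude, eyes-closed alpha gain and shared-alpha
#' coherence - with covariates matching the demographic profile of a male
#' cohort in its fifties and planted feature-covariate correlations.
#'
#' @param n_per_group Named counts per group (each at least 2).
#' @param sample_rate Sampling rate in Hz.
#' @param duration Recording duration per condition in seconds (at least
#'   4 s, i.e. two epochs).
#' @param montage Ordered channel labels.
#' @param band_amplitude Tibble `band` x group columns: RMS amplitude
#'   (microvolts) of each band-limited component, per group.
#' @param background_rms RMS amplitude of the 1/f background component.
#' @param background_exponent Spectral slope of the background (power
#'   density proportional to `1/f^exponent`).
#' @param alpha_ec_gain Named multiplicative eyes-closed over eyes-open
#'   alpha amplitude factor per group (at least 1).
#' @param alpha_shared_fraction Named fraction in `[0, 1]` of alpha
#'   variance driven by the shared source, per group.
#' @param subject_sdlog Log-SD of the per-subject band amplitude jitter.
#' @param covariate_spec Per-covariate, per-group mean, SD, bounds,
#'   missing rate and integer flag.
#' @param planted_correlations Tibble of (covariate, feature, r) target
#'   correlations planted between covariates and realized EEG features.
#' @param spikes Optional tibble (`subject`, `condition`, `epoch`,
#'   `amplitude`) of artifact spikes to inject, used to exercise epoch
#'   rejection.
#' @param power_outliers Optional tibble (`subject`, `condition`, `scale`)
#'   of whole-recording amplitude scalings, used to exercise the
#'   spectral-power outlier screen.
#' @param seed Integer master seed; the whole cohort is a deterministic
#'   function of the configuration and this seed.
#' @return An `effect_config` object (a validated list).
#' @export
effect_config <- function(n_per_group = c(never = 33, past = 28, smoker = 20),
                          sample_rate = 500,
                          duration = 180,
                          montage = default_montage(),
                          band_amplitude = default_band_amplitude(),
                          background_rms = 3,
                          background_exponent = 1,
                          alpha_ec_gain = c(never = 1.3, past = 1.3, smoker = 1.6),
                          alpha_shared_fraction = c(never = 0.15, past = 0.20, smoker = 0.45),
                          subject_sdlog = 0.15,
                          covariate_spec = default_covariate_spec(),
                          planted_correlations = default_planted_correlations(),
                          spikes = NULL,
                          power_outliers = NULL,
                          seed = 20230308) {
  groups <- names(n_per_group)
  if (is.null(groups) || any(!nzchar(groups))) {
    abort_bad_input("`n_per_group` must be a named vector of group counts.")
  }
  if (any(n_per_group < 2)) {
    abort_bad_input("Each group needs at least 2 subjects.")
  }
  if (duration < 4) {
    abort_bad_input("`duration` must be at least 4 s (two epochs).")
  }
  if (sample_rate <= 100) {
    abort_bad_input("`sample_rate` must exceed 100 Hz.")
  }
  if (!all(groups %in% names(band_amplitude))) {
    abort_bad_input("`band_amplitude` must have one column per group.")
  }
  if (any(as.matrix(band_amplitude[groups]) < 0) || background_rms < 0) {
    abort_bad_input("Amplitudes must be non-negative.")
  }
  if (!all(groups %in% names(alpha_ec_gain)) || any(alpha_ec_gain < 1)) {
    abort_bad_input("`alpha_ec_gain` needs a value >= 1 for every group.")
  }
  if (!all(groups %in% names(alpha_shared_fraction)) ||
    any(alpha_shared_fraction < 0) || any(alpha_shared_fraction > 1)) {
    abort_bad_input("`alpha_shared_fraction` must lie in [0, 1] for every group.")
  }
  structure(
    list(
      n_per_group = n_per_group,
      groups = groups,
      sample_rate = sample_rate,
      duration = duration,
      montage = montage,
      band_amplitude = band_amplitude,
      background_rms = background_rms,
      background_exponent = background_exponent,
      alpha_ec_gain = alpha_ec_gain,
      alpha_shared_fraction = alpha_shared_fraction,
      subject_sdlog = subject_sdlog,
      covariate_spec = covariate_spec,
      planted_correlations = planted_correlations,
      spikes = spikes,
      power_outliers = power_outliers,
      seed = as.integer(seed)
    ),
    class = "effect_config"
  )
}

#' Cohort presets
#'
#' `paper_preset()` is the default configuration of [effect_config()]: a
#' 33/28/20 never/past/smoker cohort with a theta deficit in both smoker
#' groups and alpha effects (power, eyes-closed gain, shared-source
#' coherence) in current smokers only. `null_preset()` keeps the cohort
#' structure but removes every group difference and planted correlation;
#' it is the negative control used to check false-positive rates.
#'
#' @param ... Overrides forwarded to [effect_config()] (e.g. a smaller
#'   `duration` or `sample_rate` for quick runs).
#' @return An `effect_config`.
#' @export
paper_preset <- function(...) {
  effect_config(...)
}

#' @rdname paper_preset
#' @export
null_preset <- function(...) {
  amp <- default_band_amplitude()
  amp$past <- amp$never
  amp$smoker <- amp$never
  args <- list(
    band_amplitude = amp,
    alpha_ec_gain = c(never = 1.3, past = 1.3, smoker = 1.3),
    alpha_shared_fraction = c(never = 0.2, past = 0.2, smoker = 0.2),
    planted_correlations = default_planted_correlations()[0, ]
  )
  overrides <- list(...)
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  do.call(effect_config, args)
}

#' @export
print.effect_config <- function(x, ...) {
  cat("<effect_config>\n")
  cat(sprintf(
    "  groups: %s\n",
    paste(sprintf("%s (n=%d)", x$groups, x$n_per_group), collapse = ", ")
  ))
  cat(sprintf(
    "  %d channels, %g Hz, %g s per condition, seed %d\n",
    length(x$montage), x$sample_rate, x$duration, x$seed
  ))
  cat(sprintf(
    "  alpha EC gain: %s; shared fraction: %s\n",
    paste(sprintf("%s=%.2f", x$groups, x$alpha_ec_gain[x$groups]), collapse = " "),
    paste(sprintf("%s=%.2f", x$groups, x$alpha_shared_fraction[x$groups]), collapse = " ")
  ))
  invisible(x)
}

# Subject table for a configured cohort: ids, groups, per-subject seeds.
cohort_subjects <- function(config) {
  groups <- rep(config$groups, times = config$n_per_group)
  idx <- unlist(lapply(config$n_per_group, seq_len), use.names = FALSE)
  tibble::tibble(
    subject = sprintf("%s%02d", groups, idx),
    group = groups,
    subject_seed = child_seed(config$seed, seq_along(groups))
  )
}

#' Write / read an effect configuration as plain text
#'
#' Serializes the configuration (including its data-frame fields) to a
#' YAML file so that a run can be reproduced from disk.
#'
#' @param config An `effect_config`.
#' @param path File path.
#' @return `write_effect_config()` returns `path` invisibly;
#'   `read_effect_config()` returns the restored `effect_config`.
#' @export
write_effect_config <- function(config, path) {
  stopifnot(inherits(config, "effect_config"))
  ser <- lapply(unclass(config), function(f) {
    if (is.data.frame(f)) {
      lapply(as.list(f), identity)
    } else if (is.atomic(f) && !is.null(names(f))) {
      as.list(f) # named vectors serialize as YAML maps
    } else {
      f
    }
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_effect_config
#' @export
read_effect_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("Config file '%s' not found.", path))
  raw <- yaml::read_yaml(path)
  to_tbl <- function(x) {
    if (is.null(x)) return(NULL)
    x <- lapply(x, unlist)
    x <- x[lengths(x) > 0]
    if (!length(x)) return(NULL)
    tibble::as_tibble(x)
  }
  effect_config(
    n_per_group = unlist(raw$n_per_group),
    sample_rate = raw$sample_rate,
    duration = raw$duration,
    montage = unlist(raw$montage),
    band_amplitude = to_tbl(raw$band_amplitude),
    background_rms = raw$background_rms,
    background_exponent = raw$background_exponent,
    alpha_ec_gain = unlist(raw$alpha_ec_gain),
    alpha_shared_fraction = unlist(raw$alpha_shared_fraction),
    subject_sdlog = raw$subject_sdlog,
    covariate_spec = to_tbl(raw$covariate_spec),
    planted_correlations = to_tbl(raw$planted_correlations) %||% default_planted_correlations()[0, ],
    spikes = to_tbl(raw$spikes),
    power_outliers = to_tbl(raw$power_outliers),
    seed = raw$seed
  )
}
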