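# Signal synthesis: band-limited Gaussian components plus 1/f background.

# Squared-magnitude response of a Butterworth band (high-pass and low-pass
# sections), evaluated on folded FFT frequencies in Hz. This equals the
# amplitude response of the corresponding zero-phase (forward-backward)
# filter.
butter_band_mask2 <- function(freq, f_low, f_high, order = 8) {
  f <- pmax(freq, 1e-9)
  (1 / (1 + (f_low / f)^(2 * order))) * (1 / (1 + (f / f_high)^(2 * order)))
}

# Shape white noise (samples x k matrix) by an amplitude mask over FFT bins
# and normalize each column to unit RMS within the bins selected by
# `norm_sel` (in-band bins for band components), so that the realized
# in-band RMS of an amplitude-scaled component equals its configured value.
shape_noise <- function(noise, mask_amp, norm_sel = NULL) {
  m <- nrow(noise)
  ft <- stats::mvfft(noise) * mask_amp
  sel <- norm_sel %||% rep(TRUE, m)
  v <- colSums(Mod(ft[sel, , drop = FALSE])^2) / m^2
  shaped <- Re(stats::mvfft(ft, inverse = TRUE)) / m
  sweep(shaped, 2, sqrt(v), "/")
}

folded_freqs <- function(n, sample_rate) {
  f <- (0:(n - 1)) * sample_rate / n
  pmin(f, sample_rate - f)
}

# Per-subject realized parameters: amplitude jitter shared across conditions
# and the channel polarities of the shared alpha source.
subject_params <- function(config, group, subject_seed) {
  nb <- nrow(config$band_amplitude)
  nch <- length(config$montage)
  with_seed(subject_seed, {
    mult <- stats::rlnorm(nb, meanlog = 0, sdlog = config$subject_sdlog)
    polarity <- sample(c(-1, 1), nch, replace = TRUE)
    list(band_mult = stats::setNames(mult, config$band_amplitude$band), polarity = polarity)
  })
}

#' Generate one synthetic resting-state EEG recording
#'
#' Synthesizes a multichannel recording for one subject and condition as a
#' sum of independent band-limited Gaussian components (4th-order
#' Butterworth band shaping, one component per frequency band, each scaled
#' to its configured RMS amplitude) plus a 1/f-type background. The alpha
#' component of each channel mixes a single shared source (weight
#' `sqrt(shared_fraction)`, with a subject-specific polarity per channel)
#' with a channel-private source (weight `sqrt(1 - shared_fraction)`), which
#' induces inter-channel alpha coherence while leaving the per-channel alpha
#' RMS at its configured value. Eyes-closed recordings multiply the alpha
#' amplitude by the group's `alpha_ec_gain`. The output is a deterministic
#' function of (config, subject_seed, condition).
#'
#' @param group Group label; must be one of the configured groups.
#' @param condition `"EC"` or `"EO"`.
#' @param config An [effect_config()].
#' @param subject_seed Integer seed identifying the subject.
#' @param subject_id Optional subject identifier stored in the recording.
#' @return An [eeg_recording()] in microvolts.
#' @export
generate_recording <- function(group, condition, config, subject_seed,
                               subject_id = NULL) {
  stopifnot(inherits(config, "effect_config"))
  if (!group %in% config$groups) {
    abort_unknown_label(sprintf(
      "Unknown group '%s' (configured: %s).", group,
      paste(config$groups, collapse = ", ")
    ))
  }
  if (!condition %in% c("EC", "EO")) {
    abort_unknown_label(sprintf("Unknown condition '%s' (expected 'EC' or 'EO').", condition))
  }
  n <- round(config$sample_rate * config$duration)
  if (n < 2 * round(2 * config$sample_rate)) {
    abort_bad_input("Duration must cover at least two 2-second epochs.")
  }
  subject_id <- subject_id %||% sprintf("%s_seed%d", group, subject_seed)
  nch <- length(config$montage)
  pars <- subject_params(config, group, subject_seed)
  freq <- folded_freqs(n, config$sample_rate)
  bands <- config$band_amplitude
  sf <- config$alpha_shared_fraction[[group]]

  signal_seed <- child_seed(subject_seed, 1L, stream = if (condition == "EC") 1L else 2L)
  data <- with_seed(signal_seed, {
    acc <- matrix(0, n, nch)
    for (i in seq_len(nrow(bands))) {
      amp <- bands[[group]][i] * pars$band_mult[i]
      be <- eeg_bands()[eeg_bands()$band == bands$band[i], ]
      mask <- butter_band_mask2(freq, be$f_low, be$f_high)
      sel <- freq >= be$f_low & freq < be$f_high
      if (bands$band[i] == "alpha") {
        if (condition == "EC") amp <- amp * config$alpha_ec_gain[[group]]
        private <- shape_noise(matrix(stats::rnorm(n * nch), n, nch), mask, sel)
        shared <- shape_noise(matrix(stats::rnorm(n), n, 1), mask, sel)[, 1]
        comp <- sqrt(sf) * outer(shared, pars$polarity) + sqrt(1 - sf) * private
        acc <- acc + amp * comp
      } else if (amp > 0) {
        acc <- acc + amp * shape_noise(matrix(stats::rnorm(n * nch), n, nch), mask, sel)
      }
    }
    if (config$background_rms > 0) {
      bg_mask <- sqrt(
        butter_band_mask2(freq, 1, 50, order = 4) *
          pmax(freq, 0.5)^(-config$background_exponent)
      )
      sel_bg <- freq >= 1 & freq < 50
      acc <- acc + config$background_rms *
        shape_noise(matrix(stats::rnorm(n * nch), n, nch), bg_mask, sel_bg)
    }
    t(acc)
  })

  # injected artifacts: amplitude spikes in known epochs
  if (!is.null(config$spikes)) {
    hits <- config$spikes[
      config$spikes$subject == subject_id & config$spikes$condition == condition,
    ]
    if (nrow(hits)) {
      ep_len <- round(2 * config$sample_rate)
      spike_len <- max(3L, round(0.1 * config$sample_rate))
      pulse <- sin(pi * seq_len(spike_len) / spike_len)
      for (j in seq_len(nrow(hits))) {
        start <- (hits$epoch[j] - 1) * ep_len + ep_len %/% 4
        idx <- start + seq_len(spike_len)
        data[1, idx] <- data[1, idx] + hits$amplitude[j] * pulse
      }
    }
  }
  if (!is.null(config$power_outliers)) {
    hits <- config$power_outliers[
      config$power_outliers$subject == subject_id &
        config$power_outliers$condition == condition,
    ]
    if (nrow(hits)) data <- data * hits$scale[1]
  }

  eeg_recording(
    data = data,
    sample_rate = config$sample_rate,
    channel_labels = config$montage,
    subject_id = subject_id,
    group = group,
    condition = condition
  )
}
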