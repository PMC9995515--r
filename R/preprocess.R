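# Preprocessing: band-pass filtering, common average reference, epoching,
# and the two quantitative artifact criteria.

# Squared magnitude of an IIR filter evaluated on digital frequencies w (rad).
freq_response2 <- function(flt, w) {
  z <- exp(-1i * w)
  num <- outer(z, seq_along(flt$b) - 1L, "^") %*% flt$b
  den <- outer(z, seq_along(flt$a) - 1L, "^") %*% flt$a
  Mod(drop(num) / drop(den))^2
}

# Zero-phase band-pass applied to a samples x channels matrix.
#
# The filter is a cascade of Butterworth high-pass (order 4) and low-pass
# (order 8) sections. Zero-phase response (the squared magnitude, as produced
# by forward-backward filtering at steady state) is applied in the frequency
# domain after reflective padding, which removes edge transients and is much
# faster than per-channel time-domain recursion.
zp_bandpass_matrix <- function(x, sample_rate, low, high) {
  n <- nrow(x)
  np <- min(n - 1L, round(2 * sample_rate))
  pad_top <- 2 * x[rep(1L, np), , drop = FALSE] - x[(np + 1L):2L, , drop = FALSE]
  pad_bot <- 2 * x[rep(n, np), , drop = FALSE] - x[(n - 1L):(n - np), , drop = FALSE]
  xp <- rbind(pad_top, x, pad_bot)
  m <- nrow(xp)
  hp <- signal::butter(4, low / (sample_rate / 2), type = "high")
  lp <- signal::butter(8, high / (sample_rate / 2), type = "low")
  w <- 2 * pi * (0:(m - 1)) / m
  w <- pmin(w, 2 * pi - w)
  gain <- freq_response2(hp, w) * freq_response2(lp, w)
  y <- Re(stats::mvfft(stats::mvfft(xp) * gain, inverse = TRUE)) / m
  y[(np + 1L):(np + n), , drop = FALSE]
}

#' Band-pass filter a recording
#'
#' Applies a zero-phase Butterworth band-pass (high-pass order 4, low-pass
#' order 8) to every channel. The default 1-50 Hz band removes DC drift and
#' attenuates mains-frequency and other out-of-band components: power one
#' octave beyond the band edges is suppressed by more than 20 dB, and a pure
#' 60 Hz tone retains less than 10 percent of its RMS amplitude.
#'
#' @param recording An [eeg_recording()].
#' @param low,high Band edges in Hz; `0 < low < high < sample_rate/2`.
#' @return A filtered `eeg_recording`.
#' @export
eeg_bandpass <- function(recording, low = 1, high = 50) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sample_rate
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || low >= high || high >= fs / 2) {
    abort_bad_input(sprintf(
      "Invalid band (%g, %g) Hz: need 0 < low < high < sample_rate/2 = %g.",
      low, high, fs / 2
    ))
  }
  filtered <- t(zp_bandpass_matrix(t(recording$data), fs, low, high))
  out <- recording
  out$data <- filtered
  out
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' that at every sample the channel mean is zero. The operation is
#' idempotent.
#'
#' @param recording An [eeg_recording()] with at least two channels.
#' @return A re-referenced `eeg_recording`.
#' @export
rereference_car <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(recording$data) < 2) {
    abort_bad_input("Common average reference needs at least 2 channels.")
  }
  out <- recording
  out$data <- sweep(recording$data, 2, colMeans(recording$data))
  out
}

#' Slice a recording into fixed-length epochs
#'
#' Cuts the signal into consecutive non-overlapping epochs of
#' `epoch_length` seconds; a trailing partial segment is dropped, so the
#' number of epochs is `floor(duration / epoch_length)`.
#'
#' @param recording An [eeg_recording()].
#' @param epoch_length Epoch length in seconds (default 2, giving 0.5 Hz
#'   spectral resolution).
#' @return An `eeg_epochs` object.
#' @export
make_epochs <- function(recording, epoch_length = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!is.numeric(epoch_length) || length(epoch_length) != 1 || epoch_length <= 0) {
    abort_bad_input("`epoch_length` must be a positive number of seconds.")
  }
  samples_per <- round(recording$sample_rate * epoch_length)
  n_samples <- ncol(recording$data)
  n_ep <- n_samples %/% samples_per
  if (n_ep < 1) {
    abort_bad_input(sprintf(
      "Recording too short: %.3f s but epoch length is %g s.",
      n_samples / recording$sample_rate, epoch_length
    ))
  }
  used <- recording$data[, seq_len(n_ep * samples_per), drop = FALSE]
  dim(used) <- c(nrow(recording$data), samples_per, n_ep)
  new_eeg_epochs(
    data = used,
    sample_rate = recording$sample_rate,
    channel_labels = recording$channel_labels,
    epoch_length = epoch_length,
    subject_id = recording$subject_id,
    group = recording$group,
    condition = recording$condition
  )
}

#' Reject epochs on an absolute amplitude criterion
#'
#' Marks as rejected every epoch in which any sample on any channel exceeds
#' `threshold` microvolts in absolute value (the absolute, not peak-to-peak,
#' reading of the criterion). If all epochs are rejected the
#' subject-by-condition is flagged as excluded.
#'
#' @param epochs An `eeg_epochs` object.
#' @param threshold Amplitude threshold in microvolts (default 75).
#' @return The `eeg_epochs` object with updated `retained` flags.
#' @export
reject_amplitude <- function(epochs, threshold = 75) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort_bad_input("`threshold` must be a single positive value (microvolts).")
  }
  peak <- apply(abs(epochs$data), 3, max)
  bad <- peak > threshold
  epochs$retained <- epochs$retained & !bad
  epochs$exclusion$amplitude <- !any(epochs$retained)
  epochs
}

#' Flag spectral-power outlier subjects per condition
#'
#' Implements the second artifact criterion: a subject-by-condition is
#' excluded from statistical analysis when its total 1-50 Hz spectral power
#' (summed over bands, averaged over channels) deviates more than
#' `sd_threshold` standard deviations from its group's mean for that
#' condition. Exclusion is per condition: a subject flagged in one condition
#' still contributes the other condition's features.
#'
#' The group mean and SD include the subject under test. A consequence of
#' this definition is that the z-score is bounded by `(n-1)/sqrt(n)`, so
#' the 3 SD criterion cannot fire in groups of fewer than about a dozen
#' subjects; at the 20-33 subjects per group of a typical cohort a
#' genuinely extreme recording is detected reliably.
#'
#' @param features Feature table as returned by the spectral stage, with
#'   columns `subject`, `group`, `condition`, `channel`, `band`,
#'   `abs_power`.
#' @param sd_threshold Number of standard deviations (default 3).
#' @return Inclusion mask: a tibble with one row per subject x condition and
#'   columns `subject`, `group`, `condition`, `total_power`, `z`,
#'   `included`. The feature table itself is left untouched.
#' @export
exclude_power_outliers <- function(features, sd_threshold = 3) {
  need <- c("subject", "group", "condition", "channel", "band", "abs_power")
  if (!is.data.frame(features) || !all(need %in% names(features))) {
    abort_bad_input(paste(
      "`features` must contain columns", paste(need, collapse = ", ")
    ))
  }
  if (!is.numeric(sd_threshold) || sd_threshold <= 0) {
    abort_bad_input("`sd_threshold` must be positive.")
  }
  totals <- features |>
    dplyr::group_by(.data$subject, .data$group, .data$condition, .data$channel) |>
    dplyr::summarise(channel_total = sum(.data$abs_power), .groups = "drop") |>
    dplyr::group_by(.data$subject, .data$group, .data$condition) |>
    dplyr::summarise(total_power = mean(.data$channel_total), .groups = "drop")

  counts <- totals |> dplyr::count(.data$group, .data$condition)
  if (any(counts$n < 3)) {
    abort_degenerate(
      "Each group needs at least 3 subjects per condition for the SD criterion."
    )
  }
  totals |>
    dplyr::group_by(.data$group, .data$condition) |>
    dplyr::mutate(
      z = if (stats::sd(.data$total_power) > 0) {
        (.data$total_power - mean(.data$total_power)) / stats::sd(.data$total_power)
      } else {
        rep(0, dplyr::n())
      },
      included = abs(.data$z) <= sd_threshold
    ) |>
    dplyr::ungroup()
}

#' Preprocess a raw recording end to end
#'
#' Convenience wrapper chaining the standard preprocessing stages:
#' band-pass filter (1-50 Hz), common average reference, two-second
#' epoching and absolute-amplitude epoch rejection.
#'
#' @param recording An [eeg_recording()].
#' @param low,high Band-pass edges in Hz.
#' @param car Apply the common average reference? Default `TRUE`.
#' @param epoch_length Epoch length in seconds.
#' @param amp_threshold Amplitude rejection threshold in microvolts.
#' @return An `eeg_epochs` object with artifact flags set.
#' @export
preprocess_recording <- function(recording, low = 1, high = 50, car = TRUE,
                                 epoch_length = 2, amp_threshold = 75) {
  out <- eeg_bandpass(recording, low, high)
  if (car) out <- rereference_car(out)
  out <- make_epochs(out, epoch_length)
  reject_amplitude(out, amp_threshold)
}
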