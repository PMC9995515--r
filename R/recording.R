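#' Construct a multichannel EEG recording
#'
#' A recording holds one subject-by-condition multichannel signal together
#' with its montage and sampling-rate metadata. Signals are stored as a
#' channels-by-samples matrix in microvolts.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param sample_rate Sampling rate in Hz. Must exceed 100 Hz so that the
#'   1-50 Hz analysis band is below Nyquist.
#' @param channel_labels Character vector of channel labels, one per row of
#'   `data`.
#' @param subject_id Subject identifier.
#' @param group Group label, typically one of `"never"`, `"past"`,
#'   `"smoker"`.
#' @param condition Recording condition, `"EC"` (eyes-closed) or `"EO"`
#'   (eyes-open).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sample_rate, channel_labels,
                          subject_id = "s001", group = NA_character_,
                          condition = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort_bad_input("`data` must be a numeric channels-by-samples matrix.")
  }
  if (!all(is.finite(data))) {
    abort_bad_input("Recording contains non-finite samples.")
  }
  if (length(channel_labels) != nrow(data)) {
    abort_bad_input("`channel_labels` must have one entry per data row.")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 100) {
    abort_bad_input("`sample_rate` must be a single value above 100 Hz (Nyquist for the 1-50 Hz band).")
  }
  if (!is.na(condition) && !condition %in% c("EC", "EO")) {
    abort_unknown_label(sprintf("Unknown condition '%s' (expected 'EC' or 'EO').", condition))
  }
  structure(
    list(
      subject_id = subject_id,
      group = group,
      condition = condition,
      sample_rate = sample_rate,
      channel_labels = as.character(channel_labels),
      data = data
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s [%s, %s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$group %||% NA, x$condition %||% NA,
    nrow(x$data), ncol(x$data), x$sample_rate, ncol(x$data) / x$sample_rate
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  ncol(recording$data) / recording$sample_rate
}

#' @method tidy eeg_recording
#' @export
tidy.eeg_recording <- function(x, ...) {
  tibble::tibble(
    subject = x$subject_id,
    group = x$group,
    condition = x$condition,
    channel = rep(x$channel_labels, each = ncol(x$data)),
    time = rep(seq_len(ncol(x$data)) / x$sample_rate, times = nrow(x$data)),
    amplitude = as.vector(t(x$data))
  )
}
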