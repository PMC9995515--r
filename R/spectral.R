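# Spectral features: per-epoch power spectra, band powers, relative power,
# eyes-closed/eyes-open reactivity, channel averages.

# Power spectrum of a samples x channels matrix; one-sided, normalized so the
# bin sum equals the (population) variance of each demeaned channel.
psd_matrix <- function(x, sample_rate, demean = TRUE) {
  n <- nrow(x)
  if (demean) x <- sweep(x, 2, colMeans(x))
  ft <- stats::mvfft(x)
  half <- floor(n / 2)
  idx <- 1:(half + 1)                      # DC .. Nyquist (or highest bin)
  p <- Mod(ft[idx, , drop = FALSE])^2 / n^2
  dbl <- rep(2, length(idx))
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(idx)] <- 1   # Nyquist bin is not mirrored
  p <- p * dbl
  list(freq = (idx - 1) * sample_rate / n, power = p)
}

#' Power spectrum of a single epoch
#'
#' Computes the FFT periodogram of each channel of one epoch. The epoch is
#' mean-corrected per channel and no taper is applied, so Parseval's
#' identity holds exactly: the bin sum equals the channel variance
#' (computed with denominator n), and a sinusoid at a bin frequency places
#' all of its power (amplitude squared over two) in that single bin. A
#' two-second epoch gives 0.5 Hz resolution.
#'
#' @param epoch Numeric channels x samples matrix (microvolts), or a vector
#'   for a single channel.
#' @param sample_rate Sampling rate in Hz.
#' @param channel_labels Optional channel labels.
#' @return A tibble with columns `channel`, `freq` (Hz) and `power`
#'   (microvolts squared).
#' @export
epoch_psd <- function(epoch, sample_rate, channel_labels = NULL) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  if (!is.numeric(epoch) || !all(is.finite(epoch))) {
    abort_bad_input("Epoch contains non-finite samples.")
  }
  labels <- channel_labels %||% paste0("ch", seq_len(nrow(epoch)))
  ps <- psd_matrix(t(epoch), sample_rate)
  tibble::tibble(
    channel = rep(labels, each = length(ps$freq)),
    freq = rep(ps$freq, times = nrow(epoch)),
    power = as.vector(ps$power)
  )
}

# Map spectral bins to bands; rows of `power` are bins. Returns band x channel.
band_power_matrix <- function(freq, power, bands) {
  out <- matrix(0, nrow(bands), ncol(power),
    dimnames = list(bands$band, colnames(power))
  )
  for (i in seq_len(nrow(bands))) {
    sel <- freq >= bands$f_low[i] & freq < bands$f_high[i]
    out[i, ] <- colSums(power[sel, , drop = FALSE])
  }
  out
}

#' Absolute band powers from a power spectrum
#'
#' Sums spectral bins into frequency bands using the half-open convention
#' `f_low <= f < f_high`, so a 4.0 Hz bin counts toward theta, not delta.
#' With the default band table the five band powers add up exactly to the
#' total 1-50 Hz power.
#'
#' @param psd Tibble from [epoch_psd()] (columns `channel`, `freq`,
#'   `power`).
#' @param bands Band definition table; defaults to [eeg_bands()]. Bands must
#'   lie within the analysed 1-50 Hz range.
#' @return A tibble with columns `channel`, `band`, `power`.
#' @export
band_powers <- function(psd, bands = eeg_bands()) {
  check_bands(bands)
  if (!all(c("channel", "freq", "power") %in% names(psd))) {
    abort_bad_input("`psd` must have columns channel, freq, power.")
  }
  psd |>
    dplyr::cross_join(dplyr::rename(bands, band_name = "band")) |>
    dplyr::filter(.data$freq >= .data$f_low, .data$freq < .data$f_high) |>
    dplyr::group_by(.data$channel, band = .data$band_name) |>
    dplyr::summarise(power = sum(.data$power), .groups = "drop") |>
    dplyr::mutate(band = factor(.data$band, levels = bands$band)) |>
    dplyr::arrange(.data$channel, .data$band) |>
    dplyr::mutate(band = as.character(.data$band))
}

#' Average per-epoch band powers over retained epochs
#'
#' @param epoch_powers Tibble with columns `epoch`, `channel`, `band`,
#'   `power`, and optionally a logical `retained` column; rejected epochs
#'   are excluded from the mean.
#' @return A tibble with columns `channel`, `band`, `power` (the arithmetic
#'   mean over retained epochs).
#' @export
average_band_powers <- function(epoch_powers) {
  need <- c("epoch", "channel", "band", "power")
  if (!is.data.frame(epoch_powers) || !all(need %in% names(epoch_powers))) {
    abort_bad_input("`epoch_powers` must have columns epoch, channel, band, power.")
  }
  if ("retained" %in% names(epoch_powers)) {
    epoch_powers <- dplyr::filter(epoch_powers, .data$retained)
  }
  if (nrow(epoch_powers) == 0) {
    abort_degenerate("No retained epochs to average; subject should be excluded upstream.")
  }
  epoch_powers |>
    dplyr::group_by(.data$channel, .data$band) |>
    dplyr::summarise(power = mean(.data$power), .groups = "drop")
}

#' Relative band power
#'
#' Divides each band's absolute power by the total power over all bands
#' (the full 1-50 Hz range for the default band table), per channel. The
#' resulting fractions are non-negative and sum to one within each channel.
#'
#' @param abs_powers Tibble with columns `channel`, `band`, `power`.
#' @return The input with an additional `rel_power` column.
#' @export
relative_power <- function(abs_powers) {
  if (!all(c("channel", "band", "power") %in% names(abs_powers))) {
    abort_bad_input("`abs_powers` must have columns channel, band, power.")
  }
  out <- abs_powers |>
    dplyr::group_by(.data$channel) |>
    dplyr::mutate(total = sum(.data$power)) |>
    dplyr::ungroup()
  if (any(out$total <= 0)) {
    abort_degenerate("Total spectral power is zero; relative power undefined.")
  }
  out |>
    dplyr::mutate(rel_power = .data$power / .data$total) |>
    dplyr::select(-"total")
}

#' EEG reactivity between eyes-closed and eyes-open conditions
#'
#' Reactivity is the relative power drop on eye opening:
#' `(EC - EO) / EC`, computed per band and channel. It is at most 1 (when
#' the eyes-open power vanishes), zero when the two conditions match, and
#' negative when eyes-open power exceeds eyes-closed power.
#'
#' @param ec_power Eyes-closed band power (positive).
#' @param eo_power Eyes-open band power (non-negative). Vectorised.
#' @return Unitless reactivity values.
#' @export
reactivity <- function(ec_power, eo_power) {
  if (any(!is.finite(ec_power)) || any(!is.finite(eo_power))) {
    abort_bad_input("Band powers must be finite.")
  }
  if (any(ec_power <= 0)) {
    abort_degenerate("Eyes-closed band power must be positive to define reactivity.")
  }
  (ec_power - eo_power) / ec_power
}

#' Average a feature across channels
#'
#' Collapses a per-channel feature to one value per remaining grouping
#' (typically per subject) by an unweighted mean over channels, the
#' summary used before correlating EEG features with covariates.
#'
#' @param data Tibble containing a `channel` column.
#' @param value Column to average (tidy-eval).
#' @param ... Grouping columns to keep (tidy-eval); defaults to every
#'   column other than `channel` and `value` if omitted is not supported -
#'   name the groups explicitly.
#' @return A tibble of group keys and the channel-averaged `value`.
#' @export
channel_average <- function(data, value, ...) {
  if (!is.data.frame(data) || !"channel" %in% names(data)) {
    abort_bad_input("`data` must contain a `channel` column.")
  }
  if (nrow(data) == 0) {
    abort_bad_input("Empty channel set: nothing to average.")
  }
  data |>
    dplyr::group_by(...) |>
    dplyr::summarise("{{value}}" := mean({{ value }}), .groups = "drop")
}

#' Band powers for one subject-by-condition
#'
#' Runs the per-epoch spectral procedure on the retained epochs of an
#' `eeg_epochs` object: FFT periodogram per epoch, band powers per epoch,
#' arithmetic mean over retained epochs, then relative power.
#'
#' @param epochs An `eeg_epochs` object with at least one retained epoch.
#' @param bands Band table, defaults to [eeg_bands()].
#' @return A tibble with columns `subject`, `group`, `condition`,
#'   `channel`, `band`, `abs_power`, `rel_power`; the number of epochs used
#'   is stored in the `n_epochs` attribute.
#' @export
subject_band_powers <- function(epochs, bands = eeg_bands()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  check_bands(bands)
  keep <- which(epochs$retained)
  if (length(keep) == 0) {
    abort_degenerate("No retained epochs; subject x condition is excluded.")
  }
  acc <- NULL
  freq <- NULL
  for (e in keep) {
    ps <- psd_matrix(t(epochs$data[, , e]), epochs$sample_rate)
    bp <- band_power_matrix(ps$freq, ps$power, bands)
    acc <- if (is.null(acc)) bp else acc + bp
  }
  mean_bp <- acc / length(keep)
  rel <- sweep(mean_bp, 2, colSums(mean_bp), "/")
  out <- tibble::tibble(
    subject = epochs$subject_id,
    group = epochs$group,
    condition = epochs$condition,
    channel = rep(epochs$channel_labels, each = nrow(bands)),
    band = rep(bands$band, times = length(epochs$channel_labels)),
    abs_power = as.vector(mean_bp),
    rel_power = as.vector(rel)
  )
  attr(out, "n_epochs") <- length(keep)
  out
}
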