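# Magnitude-squared coherence between channel pairs, estimated by Welch
# averaging of mean-corrected, Hann-tapered periodograms over the retained
# two-second epochs.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# FFT of windowed, per-segment mean-corrected segments.
# x: samples x channels for one segment. Returns bins x channels (full FFT).
segment_fft <- function(x, window) {
  x <- sweep(x, 2, colMeans(x))
  stats::mvfft(x * window)
}

# Cross/auto spectra averaged over segments for all channels.
# segs: list of samples x channels matrices. Returns list(freq, cross) where
# cross is an array bins x channels x channels; bins are restricted to
# `max_freq` (the analysis band) to keep the array small.
welch_cross_spectra <- function(segs, sample_rate, window = "hann",
                                max_freq = NULL) {
  n <- nrow(segs[[1]])
  w <- switch(window,
    hann = hann_window(n),
    rect = rep(1, n),
    abort_bad_input(sprintf("Unknown window '%s'.", window))
  )
  half <- floor(n / 2) + 1L
  freq <- (seq_len(half) - 1) * sample_rate / n
  if (!is.null(max_freq)) {
    half <- max(which(freq <= max_freq))
    freq <- freq[seq_len(half)]
  }
  nch <- ncol(segs[[1]])
  n_seg <- length(segs)
  # bins x channels x segments
  ft <- vapply(
    segs,
    function(s) segment_fft(s, w)[seq_len(half), , drop = FALSE],
    matrix(0 + 0i, half, nch)
  )
  cross <- array(0 + 0i, dim = c(half, nch, nch))
  for (b in seq_len(half)) {
    fb <- t(ft[b, , ]) # segments x channels
    if (nch == 1) fb <- t(fb)
    cross[b, , ] <- t(Conj(fb)) %*% fb
  }
  list(freq = freq, cross = cross / n_seg)
}

#' Magnitude-squared coherence of two signals
#'
#' Estimates `C(f) = |Pxy(f)|^2 / (Pxx(f) Pyy(f))` by Welch's method:
#' the signals are cut into consecutive non-overlapping segments
#' (two seconds by default, matching the analysis epochs), each segment is
#' mean-corrected and Hann-tapered, and the auto- and cross-periodograms
#' are averaged across segments before forming the ratio. Coherence lies in
#' `[0, 1]` at every frequency, equals 1 when the signals are identical up
#' to an affine transform, and for independent signals has expectation
#' approximately `1/L` for `L` segments.
#'
#' @param x,y Equal-length numeric signals.
#' @param sample_rate Sampling rate in Hz.
#' @param segment_length Segment length in seconds (default 2).
#' @param window Taper: `"hann"` (default) or `"rect"`.
#' @return A tibble with columns `freq` (Hz) and `coherence`; the number of
#'   segments used is stored in the `n_segments` attribute.
#' @export
msc <- function(x, y, sample_rate, segment_length = 2, window = "hann") {
  if (length(x) != length(y)) {
    abort_bad_input("`x` and `y` must have equal length.")
  }
  samples_per <- round(sample_rate * segment_length)
  n_seg <- length(x) %/% samples_per
  if (n_seg < 2) {
    abort_bad_input("Coherence needs at least 2 segments (one segment gives identically 1).")
  }
  segs <- lapply(seq_len(n_seg), function(i) {
    idx <- ((i - 1) * samples_per + 1):(i * samples_per)
    cbind(x[idx], y[idx])
  })
  ws <- welch_cross_spectra(segs, sample_rate, window)
  pxx <- Re(ws$cross[, 1, 1])
  pyy <- Re(ws$cross[, 2, 2])
  pxy <- ws$cross[, 1, 2]
  coh <- Mod(pxy)^2 / (pxx * pyy)
  out <- tibble::tibble(freq = ws$freq, coherence = coh)
  attr(out, "n_segments") <- n_seg
  out
}

#' Band-average coherence
#'
#' Unweighted mean of the frequency-resolved coherence over the bins of one
#' band (half-open interval `f_low <= f < f_high`).
#'
#' @param coherence_df Tibble from [msc()] with columns `freq`,
#'   `coherence`.
#' @param band A one-row band definition (columns `f_low`, `f_high`), e.g.
#'   a row of [eeg_bands()].
#' @return A single coherence value.
#' @export
band_coherence <- function(coherence_df, band) {
  if (!all(c("freq", "coherence") %in% names(coherence_df))) {
    abort_bad_input("`coherence_df` must have columns freq and coherence.")
  }
  sel <- coherence_df$freq >= band$f_low[1] & coherence_df$freq < band$f_high[1]
  if (!any(sel)) {
    abort_bad_input("Band contains no frequency bins.")
  }
  mean(coherence_df$coherence[sel])
}

#' Band coherence matrix over all channel pairs
#'
#' Computes the magnitude-squared coherence between every pair of channels
#' from the retained epochs (the Welch segments), averaged over the bins of
#' one frequency band. The result is symmetric with unit diagonal and all
#' entries in `[0, 1]`; 31 channels give 465 unique off-diagonal pairs.
#'
#' @param epochs An `eeg_epochs` object with at least 2 channels and 2
#'   retained epochs.
#' @param band One-row band definition; defaults to the alpha row of
#'   [eeg_bands()].
#' @param window Taper passed to the Welch estimator.
#' @return An `eeg_coherence_matrix`: the channels x channels matrix with
#'   attributes `band`, `channels` and `n_segments`.
#' @export
coherence_matrix <- function(epochs, band = dplyr::filter(eeg_bands(), band == "alpha"),
                             window = "hann") {
  stopifnot(inherits(epochs, "eeg_epochs"))
  keep <- which(epochs$retained)
  if (dim(epochs$data)[1] < 2) abort_bad_input("Need at least 2 channels.")
  if (length(keep) < 2) abort_bad_input("Need at least 2 retained epochs.")
  segs <- lapply(keep, function(e) t(epochs$data[, , e]))
  ws <- welch_cross_spectra(segs, epochs$sample_rate, window,
    max_freq = band$f_high[1])
  sel <- which(ws$freq >= band$f_low[1] & ws$freq < band$f_high[1])
  if (!length(sel)) abort_bad_input("Band contains no frequency bins.")
  nch <- dim(epochs$data)[1]
  acc <- matrix(0, nch, nch)
  for (b in sel) {
    s <- ws$cross[b, , ]
    auto <- Re(diag(s))
    acc <- acc + Mod(s)^2 / outer(auto, auto)
  }
  values <- acc / length(sel)
  dimnames(values) <- list(epochs$channel_labels, epochs$channel_labels)
  structure(values,
    class = c("eeg_coherence_matrix", "matrix", "array"),
    band = band$band[1] %||% NA_character_,
    channels = epochs$channel_labels,
    n_segments = length(keep)
  )
}

#' Mean of the lower triangle of a coherence matrix
#'
#' Coherence matrices are symmetric, so the strictly-below-diagonal entries
#' (diagonal excluded) summarise all unique channel pairs; their mean is
#' the scalar connectivity summary used per subject.
#'
#' @param m A square matrix (or `eeg_coherence_matrix`).
#' @return The mean of the strictly lower-triangular entries.
#' @export
lower_triangle_mean <- function(m) {
  m <- unclass(m)
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2) {
    abort_bad_input("`m` must be a square matrix with at least 2 channels.")
  }
  mean(m[lower.tri(m)])
}

#' Per-band pairwise coherence for one subject-by-condition
#'
#' @param epochs An `eeg_epochs` object.
#' @param bands Band table, defaults to [eeg_bands()].
#' @return A tidy tibble with one row per band and unordered channel pair:
#'   columns `subject`, `group`, `condition`, `band`, `ch_a`, `ch_b`,
#'   `coherence`.
#' @export
subject_band_coherence <- function(epochs, bands = eeg_bands()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  check_bands(bands)
  keep <- which(epochs$retained)
  if (length(keep) < 2) abort_bad_input("Need at least 2 retained epochs.")
  segs <- lapply(keep, function(e) t(epochs$data[, , e]))
  ws <- welch_cross_spectra(segs, epochs$sample_rate, "hann",
    max_freq = max(bands$f_high))
  nch <- dim(epochs$data)[1]
  low <- which(lower.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  out <- vector("list", nrow(bands))
  for (i in seq_len(nrow(bands))) {
    sel <- which(ws$freq >= bands$f_low[i] & ws$freq < bands$f_high[i])
    acc <- matrix(0, nch, nch)
    for (b in sel) {
      s <- ws$cross[b, , ]
      auto <- Re(diag(s))
      acc <- acc + Mod(s)^2 / outer(auto, auto)
    }
    cm <- acc / length(sel)
    out[[i]] <- tibble::tibble(
      subject = epochs$subject_id,
      group = epochs$group,
      condition = epochs$condition,
      band = bands$band[i],
      ch_a = epochs$channel_labels[low[, 1]],
      ch_b = epochs$channel_labels[low[, 2]],
      coherence = cm[low]
    )
  }
  dplyr::bind_rows(out)
}
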