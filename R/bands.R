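#' Canonical EEG frequency band table
#'
#' The five bands used throughout the pipeline: delta (1-4 Hz), theta
#' (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz) and gamma (30-50 Hz). Band
#' intervals are half-open, `[f_low, f_high)`, so the five defaults tile
#' the full 1-50 Hz analysis range exactly and every 0.5 Hz spectral bin
#' belongs to exactly one band.
#'
#' @return A tibble with columns `band`, `f_low` and `f_high` (Hz).
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band   = c("delta", "theta", "alpha", "beta", "gamma"),
    f_low  = c(1, 4, 8, 13, 30),
    f_high = c(4, 8, 13, 30, 50)
  )
}

# Validate a band table against the analysed frequency range.
check_bands <- function(bands, range = c(1, 50)) {
  if (!is.data.frame(bands) || !all(c("band", "f_low", "f_high") %in% names(bands))) {
    abort_bad_input("`bands` must be a data frame with columns band, f_low, f_high.")
  }
  if (any(bands$f_low >= bands$f_high)) {
    abort_bad_input("Each band must satisfy f_low < f_high.")
  }
  if (any(bands$f_low < range[1]) || any(bands$f_high > range[2])) {
    abort_bad_input(sprintf(
      "Bands must lie within the analysed range [%g, %g) Hz.", range[1], range[2]
    ))
  }
  invisible(bands)
}
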