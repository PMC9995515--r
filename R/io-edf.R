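# Minimal EDF (European Data Format) reader/writer for continuous
# multichannel recordings with a common integer sampling rate. Signals are
# stored as 16-bit integers with per-channel physical scaling; the
# subject/group/condition metadata are carried in the local patient
# identification field.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' Serializes an [eeg_recording()] to the European Data Format: 16-bit
#' samples, physical units microvolts, one-second data records. The
#' sampling rate must be a whole number and the recording is zero-padded
#' to a whole number of seconds. Quantization limits round-trip precision
#' to (physical range) / 65535 per channel.
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sample_rate
  if (fs != round(fs)) abort_bad_input("EDF export needs an integer sampling rate.")
  data <- recording$data
  nch <- nrow(data)
  n_rec <- ceiling(ncol(data) / fs)
  if (ncol(data) < n_rec * fs) {
    data <- cbind(data, matrix(0, nch, n_rec * fs - ncol(data)))
  }
  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768
  dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  patient <- paste(recording$subject_id, recording$group %||% "X",
    recording$condition %||% "X")
  header <- paste0(
    pad_field("0", 8),
    pad_field(patient, 80),
    pad_field("resteeg synthetic rsEEG", 80),
    pad_field("01.01.20", 8),
    pad_field("00.00.00", 8),
    pad_field(256 * (1 + nch), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(nch, 4),
    paste(pad_field(recording$channel_labels, 16), collapse = ""),
    paste(rep(pad_field("", 80), nch), collapse = ""),
    paste(rep(pad_field("uV", 8), nch), collapse = ""),
    paste(pad_field(sprintf("%.8g", pmin_), 8), collapse = ""),
    paste(pad_field(sprintf("%.8g", pmax_), 8), collapse = ""),
    paste(rep(pad_field(dmin, 8), nch), collapse = ""),
    paste(rep(pad_field(dmax, 8), nch), collapse = ""),
    paste(rep(pad_field("BP:1-50Hz", 80), nch), collapse = ""),
    paste(rep(pad_field(fs, 8), nch), collapse = ""),
    paste(rep(pad_field("", 32), nch), collapse = "")
  )
  writeChar(header, con, eos = NULL)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round((data[, idx, drop = FALSE] - pmin_) * scale + dmin)
    block <- pmin(pmax(block, dmin), dmax)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_ascii <- function(con, n) trimws(readChar(con, n, useBytes = TRUE))

#' Read an EDF recording
#'
#' Reads a continuous EDF file in which every signal shares one sampling
#' rate. Files written by [write_edf()] round-trip their subject, group and
#' condition metadata through the patient identification field.
#'
#' @param path Path to an `.edf` file.
#' @return An [eeg_recording()] in the file's physical units.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("EDF file '%s' not found.", path))
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8)
  if (version != "0") abort_io("Not an EDF file (bad version field).")
  patient <- read_ascii(con, 80)
  read_ascii(con, 80) # recording id
  read_ascii(con, 8) # start date
  read_ascii(con, 8) # start time
  read_ascii(con, 8) # header bytes
  read_ascii(con, 44) # reserved
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  nch <- as.integer(read_ascii(con, 4))

  labels <- vapply(seq_len(nch), function(i) read_ascii(con, 16), "")
  for (i in seq_len(nch)) read_ascii(con, 80) # transducer
  for (i in seq_len(nch)) read_ascii(con, 8) # physical dimension
  pmin_ <- vapply(seq_len(nch), function(i) as.numeric(read_ascii(con, 8)), 0)
  pmax_ <- vapply(seq_len(nch), function(i) as.numeric(read_ascii(con, 8)), 0)
  dmin <- vapply(seq_len(nch), function(i) as.numeric(read_ascii(con, 8)), 0)
  dmax <- vapply(seq_len(nch), function(i) as.numeric(read_ascii(con, 8)), 0)
  for (i in seq_len(nch)) read_ascii(con, 80) # prefiltering
  spr <- vapply(seq_len(nch), function(i) as.integer(read_ascii(con, 8)), 0L)
  for (i in seq_len(nch)) read_ascii(con, 32) # reserved
  if (length(unique(spr)) != 1) {
    abort_io("Only EDF files with a common sampling rate are supported.")
  }

  data <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      raw <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      data[ch, idx] <- (raw - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
        (dmax[ch] - dmin[ch]) + pmin_[ch]
    }
  }
  meta <- strsplit(patient, " ", fixed = TRUE)[[1]]
  eeg_recording(
    data = data,
    sample_rate = spr[1] / rec_dur,
    channel_labels = labels,
    subject_id = meta[1] %||% "edf",
    group = if (length(meta) > 1 && meta[2] != "X") meta[2] else NA_character_,
    condition = if (length(meta) > 2 && meta[3] != "X") meta[3] else NA_character_
  )
}
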