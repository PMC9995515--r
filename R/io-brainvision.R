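# BrainVision Core Data Format reader (.vhdr header + binary .eeg data).

parse_vhdr <- function(lines) {
  section <- ""
  kv <- list()
  channels <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, ";")) next
    if (startsWith(ln, "[")) {
      section <- gsub("\\[|\\]", "", ln)
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- substr(ln, 1, eq - 1)
    val <- substr(ln, eq + 1, nchar(ln))
    if (section == "Channel Infos") {
      channels[[key]] <- strsplit(val, ",", fixed = TRUE)[[1]]
    } else {
      kv[[paste(section, key, sep = ".")]] <- val
    }
  }
  list(kv = kv, channels = channels)
}

#' Read a BrainVision recording
#'
#' Reads the BrainVision Core Data Format: a `.vhdr` text header plus a
#' binary `.eeg` data file. Multiplexed binary data in IEEE float 32 or
#' signed 16-bit integer encoding are supported; per-channel resolutions
#' from the header are applied, yielding microvolts.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @param subject_id,group,condition Optional metadata to attach.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(vhdr_path, subject_id = NULL, group = NA_character_,
                             condition = NA_character_) {
  if (!file.exists(vhdr_path)) {
    abort_io(sprintf("BrainVision header '%s' not found.", vhdr_path))
  }
  hdr <- parse_vhdr(readLines(vhdr_path, warn = FALSE))
  kv <- hdr$kv
  get <- function(key) {
    v <- kv[[key]]
    if (is.null(v)) abort_io(sprintf("Header is missing '%s'.", key))
    v
  }
  if (toupper(get("Common Infos.DataFormat")) != "BINARY") {
    abort_io("Only BINARY BrainVision data are supported.")
  }
  if (toupper(get("Common Infos.DataOrientation")) != "MULTIPLEXED") {
    abort_io("Only MULTIPLEXED channel ordering is supported.")
  }
  nch <- as.integer(get("Common Infos.NumberOfChannels"))
  fs <- 1e6 / as.numeric(get("Common Infos.SamplingInterval"))
  fmt <- toupper(get("Binary Infos.BinaryFormat"))
  data_file <- file.path(dirname(vhdr_path), get("Common Infos.DataFile"))
  if (!file.exists(data_file)) {
    abort_io(sprintf("Data file '%s' not found.", data_file))
  }

  labels <- character(nch)
  resolution <- rep(1, nch)
  for (i in seq_len(nch)) {
    info <- hdr$channels[[paste0("Ch", i)]]
    labels[i] <- info[1] %||% paste0("Ch", i)
    if (length(info) >= 3 && nzchar(info[3])) resolution[i] <- as.numeric(info[3])
  }

  sz <- file.size(data_file)
  con <- file(data_file, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    raw <- readBin(con, "integer", n = sz / 2, size = 2, endian = "little")
  } else {
    abort_io(sprintf("Unsupported BinaryFormat '%s'.", fmt))
  }
  n_samples <- length(raw) %/% nch
  data <- matrix(raw[seq_len(n_samples * nch)], nrow = nch) * resolution
  eeg_recording(
    data = data,
    sample_rate = fs,
    channel_labels = labels,
    subject_id = subject_id %||% tools::file_path_sans_ext(basename(vhdr_path)),
    group = group,
    condition = condition
  )
}
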