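# Internal fixture format: float64 binary array + YAML sidecar. Exact
# round-trip, used for fast intermediate storage in pipelines and tests.

#' Write / read the internal recording fixture format
#'
#' Stores a recording as a raw little-endian float64 array
#' (`<prefix>.dat`, channel-major) with a YAML sidecar
#' (`<prefix>.yaml`) holding the montage and metadata. Unlike EDF this
#' round-trips samples exactly.
#'
#' @param recording An [eeg_recording()].
#' @param prefix Path prefix; `.dat` and `.yaml` are appended.
#' @return `write_recording_fixture()` returns the prefix invisibly;
#'   `read_recording_fixture()` returns the restored [eeg_recording()].
#' @export
write_recording_fixture <- function(recording, prefix) {
  stopifnot(inherits(recording, "eeg_recording"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(recording$data)), con, size = 8, endian = "little")
  yaml::write_yaml(
    list(
      subject_id = recording$subject_id,
      group = recording$group,
      condition = recording$condition,
      sample_rate = recording$sample_rate,
      channel_labels = recording$channel_labels,
      n_samples = ncol(recording$data)
    ),
    paste0(prefix, ".yaml")
  )
  invisible(prefix)
}

#' @rdname write_recording_fixture
#' @export
read_recording_fixture <- function(prefix) {
  dat <- paste0(prefix, ".dat")
  meta_path <- paste0(prefix, ".yaml")
  if (!file.exists(dat) || !file.exists(meta_path)) {
    abort_io(sprintf("Fixture '%s' (.dat/.yaml) not found.", prefix))
  }
  meta <- yaml::read_yaml(meta_path)
  nch <- length(meta$channel_labels)
  con <- file(dat, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = nch * meta$n_samples, size = 8, endian = "little")
  eeg_recording(
    data = t(matrix(raw, nrow = meta$n_samples, ncol = nch)),
    sample_rate = meta$sample_rate,
    channel_labels = unlist(meta$channel_labels),
    subject_id = meta$subject_id,
    group = meta$group %||% NA_character_,
    condition = meta$condition %||% NA_character_
  )
}
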