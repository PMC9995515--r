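#' Epoched EEG data
#'
#' Internal constructor for the epoch container produced by [make_epochs()].
#' Epochs are stored as a channels x samples x n_epochs array; `retained`
#' tracks which epochs survive artifact screening.
#'
#' @keywords internal
new_eeg_epochs <- function(data, sample_rate, channel_labels, epoch_length,
                           subject_id, group, condition,
                           retained = NULL, exclusion = list()) {
  structure(
    list(
      subject_id = subject_id,
      group = group,
      condition = condition,
      sample_rate = sample_rate,
      channel_labels = channel_labels,
      epoch_length = epoch_length,
      data = data,
      retained = retained %||% rep(TRUE, dim(data)[3]),
      exclusion = exclusion
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %s [%s, %s]: %d x %g s epochs (%d retained), %d channels @ %g Hz\n",
    x$subject_id, x$group %||% NA, x$condition %||% NA,
    dim(x$data)[3], x$epoch_length, sum(x$retained), dim(x$data)[1], x$sample_rate
  ))
  if (length(x$exclusion)) {
    cat("  excluded:", paste(names(x$exclusion)[vapply(x$exclusion, isTRUE, TRUE)], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of epochs
#' @param epochs An `eeg_epochs` object.
#' @param retained_only Count only retained epochs?
#' @return Integer count.
#' @export
n_epochs <- function(epochs, retained_only = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (retained_only) sum(epochs$retained) else dim(epochs$data)[3]
}

#' Indices of rejected epochs
#' @param epochs An `eeg_epochs` object.
#' @return Integer vector of rejected epoch indices.
#' @export
rejected_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  which(!epochs$retained)
}

#' Is a subject-by-condition flagged as excluded?
#' @param epochs An `eeg_epochs` object.
#' @return Logical.
#' @export
is_excluded <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  any(vapply(epochs$exclusion, isTRUE, TRUE))
}
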