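# Internal condition helpers and small utilities.

abort_bad_input <- function(msg, ...) {
  rlang::abort(msg, class = "resteeg_error_invalid_input", ...)
}

abort_unknown_label <- function(msg, ...) {
  rlang::abort(msg, class = "resteeg_error_unknown_label", ...)
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = "resteeg_error_degenerate", ...)
}

abort_io <- function(msg, ...) {
  rlang::abort(msg, class = "resteeg_error_io", ...)
}

# Run code with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed that stays inside the 32-bit integer range.
child_seed <- function(seed, index, stream = 0L) {
  (abs(seed) + 7919 * (index - 1) + 104729 * stream) %% 2147483629 + 1
}

rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
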