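# Condition constructors. Three error classes map onto the CLI's distinct
# nonzero exit codes: io (2), validation (3), statistical degeneracy (4).

ts_error <- function(class, message, ..., call. = FALSE) {
  stop(structure(
    class = c(class, "tumorshape_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL, ...)
  ))
}

ts_io_error <- function(message, ...) {
  ts_error("tumorshape_io_error", message, ...)
}

ts_validation_error <- function(message, ...) {
  ts_error("tumorshape_validation_error", message, ...)
}

ts_stats_error <- function(message, ...) {
  ts_error("tumorshape_stats_error", message, ...)
}

#' Exit code associated with a condition
#'
#' Maps package error classes onto the CLI's exit-code contract:
#' 0 success, 2 input/output errors, 3 validation errors, 4 statistical
#' degeneracy (rank deficiency, separation, non-convergence), 1 anything else.
#'
#' @param cond A condition object.
#' @return Integer exit code.
#' @keywords internal
ts_exit_code <- function(cond) {
  if (inherits(cond, "tumorshape_io_error")) return(2L)
  if (inherits(cond, "tumorshape_validation_error")) return(3L)
  if (inherits(cond, "tumorshape_stats_error")) return(4L)
  1L
}
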