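# Internal helpers shared across modules.

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a condition class so callers
#' (and the test suite) can distinguish configuration errors from parse
#' errors from domain errors.
#'
#' @param msg message, sprintf-style with ... interpolated.
#' @param class condition class suffix, e.g. "config_error".
#' @param ... sprintf arguments.
#' @keywords internal
#' @noRd
ctl_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(paste0("ctlnc_", class), "ctlnc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, msg, class = "config_error", ...) {
  if (!isTRUE(ok)) ctl_stop(msg, class, ...)
  invisible(TRUE)
}

#' Derive a child seed from a global seed by a fixed offset
#'
#' Sub-generators use fixed offsets so that components are independently
#' reproducible under one global seed. Kept below 2^31 - 1.
#' @keywords internal
#' @noRd
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647L)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x > 0
}

is_fraction <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}
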