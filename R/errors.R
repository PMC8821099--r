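# Condition helpers. Two user-facing classes map onto the CLI exit codes:
# input problems (exit 2) and computation/selection failures (exit 3).

abort_input <- function(message, ...) {
  abort(message, class = "dtialps_input_error", ...)
}

abort_computation <- function(message, ...) {
  abort(message, class = "dtialps_computation_error", ...)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_input(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort_input(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}
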