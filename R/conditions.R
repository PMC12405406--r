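# Condition helpers. All package errors carry a subclass of "beamqa_error"
# so callers (and tests) can distinguish bad input from bad files etc.

beamqa_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "beamqa_error"), call = call))
}

abort_input      <- function(msg) beamqa_abort(msg, "beamqa_input_error")
abort_format     <- function(msg) beamqa_abort(msg, "beamqa_format_error")
abort_degenerate <- function(msg) beamqa_abort(msg, "beamqa_degenerate_error")
abort_resource   <- function(msg) beamqa_abort(msg, "beamqa_resource_error")
abort_config     <- function(msg) beamqa_abort(msg, "beamqa_config_error")

stopifnot_increasing <- function(x, what) {
  if (length(x) == 0L) abort_input(sprintf("%s must be non-empty", what))
  if (anyNA(x)) abort_input(sprintf("%s must not contain NA", what))
  if (length(x) > 1L && any(diff(x) <= 0))
    abort_input(sprintf("%s must be strictly increasing", what))
  invisible(x)
}
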