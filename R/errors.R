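# Condition classes used throughout: validation problems (bad data or config,
# CLI exit code 2) vs I/O problems (CLI exit code 3).

#' @noRd
abort_validation <- function(message, ...) {
  rlang::abort(message, class = "gpcost_validation_error", ...)
}

#' @noRd
abort_io <- function(message, ...) {
  rlang::abort(message, class = "gpcost_io_error", ...)
}
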