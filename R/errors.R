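# Typed error conditions: every malformed input is rejected with a classed
# condition so callers (and the CLI exit-code mapping) can distinguish
# configuration, validation, range and incomplete-workup failures.

abort_config <- function(message) {
  rlang::abort(message, class = "epoctr_config_error")
}

abort_validation <- function(message) {
  rlang::abort(message, class = "epoctr_validation_error")
}

abort_range <- function(message) {
  rlang::abort(message, class = "epoctr_range_error")
}

abort_workup <- function(message) {
  rlang::abort(message, class = "epoctr_incomplete_workup_error")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
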