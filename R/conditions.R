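# Classed conditions so callers (and the pipeline driver) can distinguish
# configuration, input, and stage-dependency failures.

abort_config <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("ccsmap_config_error", "ccsmap_error")))
}

abort_input <- function(msg) {
  stop(errorCondition(msg, class = c("ccsmap_input_error", "ccsmap_error")))
}

abort_dependency <- function(msg) {
  stop(errorCondition(msg, class = c("ccsmap_dependency_error", "ccsmap_error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
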