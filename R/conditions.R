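# Classed conditions so callers (and the command-line driver) can map
# failure kinds to exit codes without string matching.

scrisk_abort <- function(message, class) {
  stop(structure(
    class = c(class, "scrisk_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_validation <- function(message) scrisk_abort(message, "scrisk_validation_error")
abort_config     <- function(message) scrisk_abort(message, "scrisk_config_error")
abort_input      <- function(message) scrisk_abort(message, "scrisk_input_error")
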