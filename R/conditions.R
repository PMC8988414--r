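# Classed conditions so callers (and the CLI) can map failure modes to
# distinct exit codes without parsing messages.

stop_coroflow <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "coroflow_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

format_error      <- function(message) stop_coroflow(message, "coroflow_format_error")
topology_error    <- function(message) stop_coroflow(message, "coroflow_topology_error")
value_error       <- function(message) stop_coroflow(message, "coroflow_value_error")
lookup_error      <- function(message) stop_coroflow(message, "coroflow_lookup_error")
calibration_error <- function(message) stop_coroflow(message, "coroflow_calibration_error")
state_error       <- function(message) stop_coroflow(message, "coroflow_state_error")
io_error          <- function(message) stop_coroflow(message, "coroflow_io_error")
join_error        <- function(message) stop_coroflow(message, "coroflow_join_error")

warn_coroflow <- function(message, class) {
  warning(warningCondition(message, class = c(class, "coroflow_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
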