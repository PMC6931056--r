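# Classed conditions so callers (and the CLI) can distinguish bad input data
# from bad configuration without string-matching messages.

abort_gait <- function(message, class) {
  stop(structure(
    class = c(class, "gait_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# usage/config problems -> exit code 1; data problems -> exit code 2
gait_config_error     <- function(msg) abort_gait(msg, "gait_config_error")
gait_format_error     <- function(msg) abort_gait(msg, "gait_format_error")
gait_validation_error <- function(msg) abort_gait(msg, "gait_validation_error")
gait_empty_error      <- function(msg) abort_gait(msg, "gait_empty_error")
gait_stat_error       <- function(msg) abort_gait(msg, "gait_stat_error")
gait_sequence_error   <- function(msg) abort_gait(msg, "gait_sequence_error")
gait_lookup_error     <- function(msg) abort_gait(msg, "gait_lookup_error")
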