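#' @keywords internal
#' @importFrom stats plogis qlogis
"_PACKAGE"

# Classed conditions so callers (and the CLI) can map failures to error
# families: format (unparseable input), config (bad options), data
# (inconsistent content), numeric (degenerate computation).

abort_attrition <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "attrition_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

format_error  <- function(msg, ...) abort_attrition("attrition_format_error", msg, ...)
config_error  <- function(msg, ...) abort_attrition("attrition_config_error", msg, ...)
data_error    <- function(msg, ...) abort_attrition("attrition_data_error", msg, ...)
numeric_error <- function(msg, ...) abort_attrition("attrition_numeric_error", msg, ...)
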