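## Condition classes shared across the package. The CLI maps them to exit
## codes: configuration -> 2, data/format -> 3, degenerate statistics -> 4.

abort_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("methinstab_config_error", "methinstab_error", "error")))
}

abort_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("methinstab_data_error", "methinstab_error", "error")))
}

abort_degenerate <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("methinstab_degenerate_error", "methinstab_error", "error")))
}
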