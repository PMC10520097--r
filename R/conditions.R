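# Classed conditions so callers (and the CLI) can map failures to exit codes.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("t1dsim_validation_error", "t1dsim_error")))
}

stop_coverage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("t1dsim_coverage_error", "t1dsim_error")))
}

stop_integrity <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("t1dsim_integrity_error", "t1dsim_error")))
}

warn_t1dsim <- function(msg, ..., class = "t1dsim_warning") {
  warning(warningCondition(sprintf(msg, ...), class = class))
}
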