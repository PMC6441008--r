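# Classed conditions so callers (and tests) can distinguish failure modes.

stop_gpcrstab <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "gpcrstab_error")))
}

warn_gpcrstab <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "gpcrstab_warning")))
}
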