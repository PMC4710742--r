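# Classed conditions so callers can distinguish configuration mistakes from
# degenerate data at run time.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("reliapower_config_error", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("reliapower_degenerate_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(name, " must be a single finite number")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_config(name, " = ", format(x), " is outside the valid range ",
                if (open_lower) "(" else "[", lower, ", ", upper,
                if (open_upper) ")" else "]")
  invisible(x)
}
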