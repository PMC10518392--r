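# Structured error signalling. Every error raised by the package carries the
# class "pedplan_error" plus a specific subclass, e.g. "pedplan_missing_structure",
# so callers (and tests) can branch on the failure mode rather than on message
# text.

stop_pedplan <- function(class, message, ...) {
  rlang::abort(message, class = c(paste0("pedplan_", class), "pedplan_error"), ...)
}

warn_pedplan <- function(class, message, ...) {
  rlang::warn(message, class = c(paste0("pedplan_", class), "pedplan_warning"), ...)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_pedplan("config_error", sprintf("`%s` must be a single finite number", name))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  if (!lo_ok || x > max) {
    stop_pedplan("config_error", sprintf(
      "`%s` = %g is outside its allowed range %s%g, %g]",
      name, x, if (strict_min) "(" else "[", min, max))
  }
  invisible(x)
}
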