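# Structured error conditions. Every error raised by the package carries
# class c("phenolscreen_<kind>", "phenolscreen_error") so callers can branch
# on the kind without parsing messages.

ps_abort <- function(message, class, ...) {
  stop(errorCondition(
    message,
    ...,
    class = c(paste0("phenolscreen_", class), "phenolscreen_error")
  ))
}

#' @noRd
ps_warn <- function(message, class) {
  warning(warningCondition(
    message,
    class = c(paste0("phenolscreen_", class), "phenolscreen_warning")
  ))
}

# Shorthand validators -------------------------------------------------------

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ps_abort(sprintf("`%s` must be a single finite number", name),
             "config_error")
  }
  bad_low <- if (strict_min) x <= min else x < min
  if (bad_low || x > max) {
    ps_abort(sprintf("`%s` = %s is outside its valid range", name,
                     format(x)), "config_error")
  }
  invisible(x)
}
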