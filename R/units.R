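# Unit conversion constants. All user-facing quantities stay in clinical units
# (cmH2O, L/min, L, s, mm); SI appears only inside hydraulic formulas.

#' @keywords internal
CMH2O_PER_PA <- 1 / 98.0665

#' @keywords internal
PA_PER_CMH2O <- 98.0665

# L/min -> m^3/s
#' @keywords internal
M3S_PER_LMIN <- 1 / 60000

# mm -> m
#' @keywords internal
M_PER_MM <- 1e-3

#' @keywords internal
stop_config <- function(field, msg) {
  rlang::abort(
    sprintf("invalid `%s`: %s", field, msg),
    class = "ventsplitr_config_error",
    field = field
  )
}

#' @keywords internal
stop_domain <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "ventsplitr_domain_error")
}

#' @keywords internal
check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(field, "must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    stop_config(field, sprintf("must be > %g", lower))
  }
  if (!strict_lower && x < lower) {
    stop_config(field, sprintf("must be >= %g", lower))
  }
  if (x > upper) stop_config(field, sprintf("must be <= %g", upper))
  invisible(x)
}
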