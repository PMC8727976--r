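#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a quadratic pressure-flow fit
#'
#' @param x A `quadratic_fit` from [fit_quadratic_law()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error` (and `boot.std.error` when bootstrapped).
#' @method tidy quadratic_fit
#' @export
tidy.quadratic_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b),
    std.error = c(x$std_error_a, x$std_error_b)
  )
  if (!is.null(x$boot_se_a)) {
    out$boot.std.error <- c(x$boot_se_a, x$boot_se_b)
  }
  out
}

#' Glance at a quadratic pressure-flow fit
#'
#' @param x A `quadratic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared` (zero-intercept),
#'   `r.squared.centered`, `nobs`, `diameter_mm`.
#' @method glance quadratic_fit
#' @export
glance.quadratic_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    r.squared.centered = x$r_squared_centered,
    nobs = x$n,
    diameter_mm = x$diameter
  )
}

#' Tidy a cross-diameter power-law model
#'
#' @param x A `powerlaw_model`.
#' @param ... Unused.
#' @return A tibble with columns `term` (quadratic/linear), `prefactor`,
#'   `exponent`.
#' @method tidy powerlaw_model
#' @export
tidy.powerlaw_model <- function(x, ...) {
  tibble::tibble(
    term = c("quadratic", "linear"),
    prefactor = c(x$k_a, x$k_b),
    exponent = c(x$m_a, x$m_b)
  )
}

#' Glance at a simulated branch
#'
#' @param x A `branch_result` from [simulate_branch()].
#' @param ... Unused.
#' @return A one-row tibble with the branch summaries: peak restrictor
#'   pressure drop (cmH2O), peak flow (L/min) and end-inspiratory volume (L).
#' @method glance branch_result
#' @export
glance.branch_result <- function(x, ...) {
  tibble::tibble(
    branch = attr(x, "label"),
    diameter_mm = attr(x, "diameter"),
    peak_pressure_drop_cmH2O = attr(x, "peak_pressure_drop"),
    peak_flow_Lmin = attr(x, "peak_flow"),
    end_inspiratory_volume_L = attr(x, "end_inspiratory_volume")
  )
}
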