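#' Restrictor pressure-flow law
#'
#' A signed quadratic relation between pressure drop and volumetric flow for a
#' splitter port with (or without) a small-bore orifice restrictor:
#' `dp = a * V |V| + b * V` with `V` in L/min and `dp` in cmH2O. The signed
#' (odd) form guarantees the restrictor only dissipates energy whatever the
#' flow direction. `a = b = 0` is the identity law, i.e. an unrestricted port.
#'
#' @param diameter Nominal restrictor bore diameter (mm), or `NA` for an
#'   unrestricted port.
#' @param a Quadratic coefficient, cmH2O (L/min)^-2. Must be >= 0.
#' @param b Linear coefficient, cmH2O (L/min)^-1. Must be >= 0.
#' @param discharge_coefficient Optional discharge coefficient in (0, 1] used
#'   for orifice-mode evaluation; `NA` when not applicable.
#'
#' @return An object of class `restrictor_law`.
#' @seealso [quadratic_pressure_drop()], [reference_coefficients()]
#' @examples
#' law <- restrictor_law(diameter = 4, a = 0.01394, b = 0.07828)
#' quadratic_pressure_drop(law, 20.4) # about 7.40 cmH2O
#' @export
restrictor_law <- function(diameter = NA_real_, a = 0, b = 0,
                           discharge_coefficient = NA_real_) {
  if (!is.na(diameter)) check_number(diameter, "diameter", 0, strict_lower = TRUE)
  check_number(a, "a", 0)
  check_number(b, "b", 0)
  if (!is.na(discharge_coefficient)) {
    if (discharge_coefficient <= 0 || discharge_coefficient > 1) {
      stop_config("discharge_coefficient", "must be in (0, 1]")
    }
  }
  structure(
    list(diameter = diameter, a = a, b = b,
         discharge_coefficient = discharge_coefficient),
    class = "restrictor_law"
  )
}

#' Identity (unrestricted-port) law
#'
#' @return A `restrictor_law` with `a = b = 0`: no added pressure drop.
#' @export
identity_law <- function() restrictor_law(diameter = NA_real_, a = 0, b = 0)

#' @export
print.restrictor_law <- function(x, ...) {
  d <- if (is.na(x$diameter)) "none" else sprintf("%g mm", x$diameter)
  cat(sprintf("<restrictor_law> D = %s, dp = %g V|V| + %g V  [cmH2O; V in L/min]\n",
              d, x$a, x$b))
  invisible(x)
}

#' Reference pressure-flow coefficients
#'
#' Quadratic pressure-flow coefficients for the reference 22 mm Y-splitter
#' with fixed orifice restrictors of 2, 3 and 4 mm bore (and the bare splitter,
#' `diameter = NA`), fitted to high-fidelity CFD simulations of the inspiratory
#' circuit. Units: `a` in cmH2O (L/min)^-2, `b` in cmH2O (L/min)^-1.
#'
#' @return A tibble with columns `diameter`, `a`, `b`, `r_squared`.
#' @examples
#' reference_coefficients()
#' @export
reference_coefficients <- function() {
  tibble::tibble(
    diameter = c(2, 3, 4, NA),
    a = c(0.22444, 0.03961, 0.01394, 0),
    b = c(0.88262, 0.26081, 0.07828, 0.00361),
    r_squared = c(0.99, 0.99, 0.99, 0.90)
  )
}

#' Reference restrictor law for a given bore diameter
#'
#' @param diameter 2, 3, 4 (mm) or `NA` / `"none"` for the bare splitter.
#' @return A [restrictor_law()] with the reference coefficients.
#' @export
reference_law <- function(diameter) {
  if (is.character(diameter) && identical(tolower(diameter), "none")) {
    diameter <- NA_real_
  }
  tab <- reference_coefficients()
  row <- if (is.na(diameter)) {
    dplyr::filter(tab, is.na(.data$diameter))
  } else {
    dplyr::filter(tab, .data$diameter == !!diameter)
  }
  if (nrow(row) != 1L) {
    stop_domain("no reference coefficients for diameter %s (have 2, 3, 4, none)",
                format(diameter))
  }
  restrictor_law(diameter = row$diameter, a = row$a, b = row$b)
}

#' Serialize a restrictor law to JSON
#'
#' Keys carry explicit unit strings so files are self-describing.
#'
#' @param law A [restrictor_law()].
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly (or the JSON string when `path` is `NULL`).
#' @export
write_law_json <- function(law, path = NULL) {
  stopifnot(inherits(law, "restrictor_law"))
  x <- list(
    diameter_mm = law$diameter,
    a_cmH2O_per_Lmin2 = law$a,
    b_cmH2O_per_Lmin = law$b,
    discharge_coefficient = law$discharge_coefficient
  )
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Read a restrictor law from JSON written by [write_law_json()]
#'
#' @param path File path.
#' @return A [restrictor_law()].
#' @export
read_law_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  restrictor_law(
    diameter = x$diameter_mm %||% NA_real_,
    a = x$a_cmH2O_per_Lmin2,
    b = x$b_cmH2O_per_Lmin,
    discharge_coefficient = x$discharge_coefficient %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
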