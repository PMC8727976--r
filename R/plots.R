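#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated branch: pressure, flow and volume over inspiration
#'
#' @param object A `branch_result` from [simulate_branch()].
#' @param ... Unused.
#' @return A ggplot with one facet per signal.
#' @method autoplot branch_result
#' @export
autoplot.branch_result <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"time_s", names_to = "signal", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~signal, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      title = sprintf("Branch '%s' inspiratory response", attr(object, "label")),
      x = "time [s]", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a titration curve
#'
#' End-inspiratory volume against inspiratory time for one branch.
#'
#' @param object A `titration_curve` from [titration_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot titration_curve
#' @export
autoplot.titration_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$inspiratory_time_s,
                               y = .data$end_volume_L)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("Tidal-volume titration, branch '%s'",
                      attr(object, "branch")),
      x = "inspiratory time [s]", y = "end-inspiratory volume [L]"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a quadratic fit over its measurements
#'
#' @param object A `quadratic_fit` from [fit_quadratic_law()].
#' @param data Optional measurement tibble (`flow_Lmin`, `dp_cmH2O`) to
#'   overlay; typically the set the law was fitted to.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot quadratic_fit
#' @export
autoplot.quadratic_fit <- function(object, data = NULL, ...) {
  fmax <- if (is.null(data)) 60 else max(data$flow_Lmin)
  curve <- tibble::tibble(
    flow_Lmin = seq(0, fmax, length.out = 200),
    dp_cmH2O = object$a * seq(0, fmax, length.out = 200)^2 +
      object$b * seq(0, fmax, length.out = 200)
  )
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$flow_Lmin,
                                           y = .data$dp_cmH2O)) +
    ggplot2::geom_line(colour = "firebrick")
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = data, alpha = 0.3)
  }
  p + ggplot2::labs(x = "flow [L/min]", y = "pressure drop [cmH2O]",
                    title = sprintf("dp = %.4g V^2 + %.4g V", object$a,
                                    object$b)) +
    ggplot2::theme_minimal()
}

#' Plot a wall profile with its low-pass trend
#'
#' @param object A `wall_profile`.
#' @param ... Unused.
#' @return A ggplot of internal radius vs axial position; the nominal radius
#'   is shown as a dashed reference line.
#' @method autoplot wall_profile
#' @export
autoplot.wall_profile <- function(object, ...) {
  nominal_r <- attr(object, "nominal_diameter") / 2
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$z_mm, y = .data$r_mm)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = nominal_r, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "axial position [mm]", y = "internal radius [mm]",
                  title = "Printed-bore wall profile (dashed: nominal)") +
    ggplot2::theme_minimal()
}
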