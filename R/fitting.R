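#' Fit a quadratic pressure-flow law to bench measurements
#'
#' Ordinary least squares of pressure drop on (flow^2, flow) with no
#' intercept: the law dp = a V^2 + b V passes through the origin by physics,
#' and fitting an intercept would absorb transducer offset that calibrated
#' instruments do not exhibit. R^2 is computed in the zero-intercept
#' convention, 1 - RSS / sum(dp^2); the mean-centred value is also reported.
#'
#' @param data A data frame with columns `flow_Lmin` and `dp_cmH2O` (a
#'   measurement set from [gen_bench_measurements()], or any tibble with
#'   those columns). Needs at least 3 distinct flows.
#' @param constrain_nonnegative If `TRUE`, a negative fitted coefficient is
#'   clipped to zero and the other refit (nested zero-intercept OLS).
#' @param n_boot Number of residual-resampling bootstrap replicates for
#'   alternative standard errors; 0 (default) to skip.
#' @param boot_seed Seed for the bootstrap resampling.
#' @return A `quadratic_fit` object with elements `a`, `b`, `std_error_a`,
#'   `std_error_b`, `r_squared` (zero-intercept), `r_squared_centered`,
#'   `n`, `diameter` (taken from the data's attribute, if any) and, when
#'   bootstrapped, `boot_se_a`/`boot_se_b`. [tidy()] and [glance()] methods
#'   are provided.
#' @examples
#' ms <- gen_bench_measurements(reference_law(2), n_reps = 5,
#'                              noise = bench_noise(seed = 1))
#' fit <- fit_quadratic_law(ms)
#' glance(fit)
#' @export
fit_quadratic_law <- function(data, constrain_nonnegative = FALSE,
                              n_boot = 0, boot_seed = 1L) {
  if (!all(c("flow_Lmin", "dp_cmH2O") %in% names(data))) {
    stop_config("data", "needs columns `flow_Lmin` and `dp_cmH2O`")
  }
  flow <- data$flow_Lmin
  dp <- data$dp_cmH2O
  if (length(unique(round(flow, 10))) < 3L) {
    rlang::abort("need at least 3 distinct flows to fit a quadratic law",
                 class = "ventsplitr_fit_error")
  }
  df <- data.frame(dp = dp, f2 = flow^2, f1 = flow)
  fit <- stats::lm(dp ~ 0 + f2 + f1, data = df)
  co <- stats::coef(fit)
  a <- unname(co["f2"]); b <- unname(co["f1"])
  if (constrain_nonnegative && (a < 0 || b < 0)) {
    if (a < 0) {
      fit <- stats::lm(dp ~ 0 + f1, data = df)
      a <- 0; b <- unname(stats::coef(fit)["f1"])
      if (b < 0) b <- 0
    } else {
      fit <- stats::lm(dp ~ 0 + f2, data = df)
      b <- 0; a <- unname(stats::coef(fit)["f2"])
      if (a < 0) a <- 0
    }
  }
  pred <- a * flow^2 + b * flow
  rss <- sum((dp - pred)^2)
  r2_zero <- 1 - rss / sum(dp^2)
  r2_cent <- 1 - rss / sum((dp - mean(dp))^2)
  # summary.lm warns on an exact fit; we only need the SE column
  se <- suppressWarnings(summary(fit)$coefficients[, "Std. Error"])
  out <- structure(
    list(
      a = a, b = b,
      std_error_a = unname(se["f2"]) %|na|% NA_real_,
      std_error_b = unname(se["f1"]) %|na|% NA_real_,
      r_squared = r2_zero,
      r_squared_centered = r2_cent,
      n = length(flow),
      diameter = attr(data, "diameter") %||% NA_real_,
      lm_fit = fit
    ),
    class = "quadratic_fit"
  )
  if (n_boot > 0) {
    boot <- boot_quadratic(flow, dp, a, b, n_boot, boot_seed)
    out$boot_se_a <- boot$se_a
    out$boot_se_b <- boot$se_b
  }
  out
}

`%|na|%` <- function(x, y) if (is.null(x) || length(x) == 0L) y else x

# residual-resampling bootstrap for (a, b)
#' @keywords internal
boot_quadratic <- function(flow, dp, a, b, n_boot, seed) {
  resid <- dp - (a * flow^2 + b * flow)
  X <- cbind(f2 = flow^2, f1 = flow)
  xtx_inv <- solve(crossprod(X))
  reps <- withr::with_seed(seed, {
    replicate(n_boot, {
      dp_star <- a * flow^2 + b * flow + sample(resid, replace = TRUE)
      drop(xtx_inv %*% crossprod(X, dp_star))
    })
  })
  list(se_a = stats::sd(reps["f2", ]), se_b = stats::sd(reps["f1", ]))
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("<quadratic_fit> dp = %.5g V^2 + %.5g V  [cmH2O; V in L/min]\n",
              x$a, x$b))
  cat(sprintf("  R^2 (zero-intercept) = %.4f, n = %d\n", x$r_squared, x$n))
  invisible(x)
}

#' Fit cross-diameter power laws to quadratic coefficients
#'
#' Given per-diameter quadratic coefficients (D, a, b), fits
#' `a = k_a D^m_a` and `b = k_b D^m_b` by ordinary least squares of log(a)
#' (resp. log(b)) on log(D). Applied to the reference coefficient table this
#' reproduces the reference meta-model dp ~ 3.55 D^-4.03 V^2 +
#' 10.27 D^-3.46 V.
#'
#' @param coefficients A data frame with columns `diameter`, `a`, `b`; at
#'   least two distinct diameters, all coefficients > 0.
#' @return A `powerlaw_model` with elements `k_a`, `m_a`, `k_b`, `m_b`.
#' @examples
#' tab <- dplyr::filter(reference_coefficients(), !is.na(diameter))
#' fit_power_laws(tab)
#' @export
fit_power_laws <- function(coefficients) {
  need <- c("diameter", "a", "b")
  if (!all(need %in% names(coefficients))) {
    stop_config("coefficients", "needs columns `diameter`, `a`, `b`")
  }
  d <- coefficients$diameter
  if (length(unique(d)) < 2L) {
    stop_domain("need at least 2 distinct diameters")
  }
  if (any(coefficients$a <= 0) || any(coefficients$b <= 0) || any(d <= 0)) {
    stop_domain("all diameters and coefficients must be positive (log fit)")
  }
  fit_one <- function(y) {
    f <- stats::lm(log(y) ~ log(d))
    co <- stats::coef(f)
    list(k = exp(unname(co[1])), m = unname(co[2]))
  }
  fa <- fit_one(coefficients$a)
  fb <- fit_one(coefficients$b)
  powerlaw_model(k_a = fa$k, m_a = fa$m, k_b = fb$k, m_b = fb$m)
}

#' Cross-diameter power-law model
#'
#' dp = k_a D^m_a V^2 + k_b D^m_b V (cmH2O; D in mm, V in L/min). Exponents
#' must be negative: pressure drop falls with bore diameter.
#'
#' @param k_a,m_a Quadratic-term prefactor and diameter exponent.
#' @param k_b,m_b Linear-term prefactor and diameter exponent.
#' @return An object of class `powerlaw_model`.
#' @export
powerlaw_model <- function(k_a, m_a, k_b, m_b) {
  if (k_a <= 0 || k_b <= 0) stop_config("k_a", "prefactors must be positive")
  if (m_a >= 0 || m_b >= 0) {
    stop_config("m_a", "diameter exponents must be negative")
  }
  structure(list(k_a = k_a, m_a = m_a, k_b = k_b, m_b = m_b),
            class = "powerlaw_model")
}

#' Reference power-law model
#'
#' The meta-fit of the reference coefficient table: parameters
#' (3.55, -4.03, 10.27, -3.46), valid for bores 2-4 mm and flows to 60 L/min.
#'
#' @return A [powerlaw_model()].
#' @export
reference_powerlaw_model <- function() {
  powerlaw_model(k_a = 3.55, m_a = -4.03, k_b = 10.27, m_b = -3.46)
}

#' @export
print.powerlaw_model <- function(x, ...) {
  cat(sprintf("<powerlaw_model> dp = %.4g D^%.4g V^2 + %.4g D^%.4g V\n",
              x$k_a, x$m_a, x$k_b, x$m_b))
  invisible(x)
}

#' Hydraulic effective diameter from a fitted quadratic coefficient
#'
#' Inverts the power-law relation k_a D^m_a = a for D: the smooth-bore
#' diameter whose quadratic coefficient matches the measured one. Useful to
#' estimate the true (as-printed) bore of an undersized part from a bench
#' test alone.
#'
#' @param fit A `quadratic_fit` (or any list with a positive `a`).
#' @param model A [powerlaw_model()]; defaults to the reference model.
#' @return Effective diameter (mm).
#' @examples
#' effective_diameter_from_fit(list(a = 0.22444)) # about 2.0 mm
#' @export
effective_diameter_from_fit <- function(fit,
                                        model = reference_powerlaw_model()) {
  a <- fit$a
  if (is.null(a) || !is.finite(a) || a <= 0) {
    stop_domain("fitted quadratic coefficient `a` must be positive")
  }
  (a / model$k_a)^(1 / model$m_a)
}
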