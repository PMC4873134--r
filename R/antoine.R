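#' Antoine vapour-pressure parameter set
#'
#' Bundles the three Antoine coefficients of the empirical law
#' \deqn{\log_{10}(P/\mathrm{kPa}) = A - \frac{B}{T/\mathrm{K} + C}}
#' together with the temperature interval spanned by the data they were
#' fitted to. Evaluation outside that interval is extrapolation and is
#' flagged with a warning, never an error: the room-temperature vapour
#' pressures of the lure compounds are themselves extrapolations from
#' boiling data collected at 0.2--101 kPa.
#'
#' @param A dimensionless Antoine coefficient.
#' @param B Antoine coefficient in kelvin; must be positive.
#' @param C Antoine temperature offset in kelvin.
#' @param T_valid_low,T_valid_high validity range in kelvin
#'   (`T_valid_low < T_valid_high`); the denominator `T + C` must be
#'   positive over the whole range.
#' @param compound optional compound label carried through to printing.
#'
#' @return An object of class `"antoine_params"`.
#' @examples
#' cl <- antoine_params(9.32104, 4291.92, -0.998176, 498.0, 587.4, "CL")
#' vapour_pressure(cl, 550)
#' @export
antoine_params <- function(A, B, C, T_valid_low, T_valid_high,
                           compound = NULL) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C),
            length(A) == 1L, length(B) == 1L, length(C) == 1L)
  if (!is.finite(B) || B <= 0)
    lv_stop("Antoine coefficient B must be positive", "lurevp_domain_error")
  if (T_valid_low >= T_valid_high)
    lv_stop("T_valid_low must be below T_valid_high", "lurevp_domain_error")
  if (T_valid_low + C <= 0)
    lv_stop("denominator T + C must be positive over the validity range",
            "lurevp_domain_error")
  structure(
    list(A = A, B = B, C = C,
         T_valid_low = T_valid_low, T_valid_high = T_valid_high,
         compound = compound),
    class = "antoine_params")
}

#' @export
print.antoine_params <- function(x, ...) {
  cat("Antoine parameters",
      if (!is.null(x$compound)) paste0("[", x$compound, "]"), "\n")
  cat(sprintf("  log10(P/kPa) = %.6g - %.6g / (T + %.6g)\n", x$A, x$B, x$C))
  cat(sprintf("  valid %.1f to %.1f K\n", x$T_valid_low, x$T_valid_high))
  invisible(x)
}

check_antoine_domain <- function(params, T) {
  if (any(T + params$C <= 0))
    lv_stop("temperature gives non-positive Antoine denominator T + C",
            "lurevp_domain_error")
}

warn_if_extrapolating <- function(params, T) {
  out <- T < params$T_valid_low | T > params$T_valid_high
  if (any(out))
    lv_warn(sprintf(
      "evaluating Antoine law%s outside validity range [%.1f, %.1f] K (extrapolation)",
      if (is.null(params$compound)) "" else paste0(" for ", params$compound),
      params$T_valid_low, params$T_valid_high),
      "lurevp_extrapolation")
}

#' Saturation vapour pressure from an Antoine law
#'
#' Evaluates `P = 10^(A - B/(T + C))` in kPa. Temperatures outside the
#' parameter set's validity range raise a `"lurevp_extrapolation"` warning.
#'
#' @param params an [antoine_params()] object.
#' @param T temperature(s) in kelvin.
#' @param warn_extrapolation emit the extrapolation warning? Default `TRUE`.
#' @return vapour pressure(s) in kPa.
#' @examples
#' rk <- antoine_params(8.86245, 3867.82, -33.3688, 506.1, 597.2, "RK")
#' suppressWarnings(vapour_pressure(rk, 298.15))  # 1.80e-6 kPa
#' @export
vapour_pressure <- function(params, T, warn_extrapolation = TRUE) {
  stopifnot(inherits(params, "antoine_params"), is.numeric(T))
  check_antoine_domain(params, T)
  if (warn_extrapolation) warn_if_extrapolating(params, T)
  10^(params$A - params$B / (T + params$C))
}

#' Boiling temperature at a given pressure (Antoine inverse)
#'
#' Closed-form inverse of the Antoine law:
#' `T = B/(A - log10 P) - C`. Round-trips with [vapour_pressure()] to
#' machine precision.
#'
#' @inheritParams vapour_pressure
#' @param P pressure(s) in kPa; must satisfy `log10(P) < A`.
#' @return boiling temperature(s) in kelvin.
#' @export
boiling_temperature <- function(params, P) {
  stopifnot(inherits(params, "antoine_params"), is.numeric(P))
  if (any(P <= 0))
    lv_stop("pressure must be positive", "lurevp_domain_error")
  if (any(log10(P) >= params$A))
    lv_stop("pressure at or above the Antoine law's asymptote 10^A",
            "lurevp_domain_error")
  params$B / (params$A - log10(P)) - params$C
}

#' Enthalpy of vaporisation from Antoine parameters
#'
#' Combines the Clausius-Clapeyron relation
#' `d ln(P)/dT = dHvap / (R T^2)` with the analytic derivative of the
#' Antoine law, giving
#' \deqn{\Delta H_{vap} = \ln(10)\, B\, R\, \frac{T^2}{(T + C)^2}}
#' with R = 8.314462 J mol^-1 K^-1.
#'
#' @inheritParams vapour_pressure
#' @return enthalpy of vaporisation in kJ mol^-1.
#' @examples
#' cl <- antoine_params(9.32104, 4291.92, -0.998176, 498.0, 587.4, "CL")
#' suppressWarnings(enthalpy_of_vaporisation(cl, 298.15))  # 82.7 kJ/mol
#' @export
enthalpy_of_vaporisation <- function(params, T, warn_extrapolation = TRUE) {
  stopifnot(inherits(params, "antoine_params"), is.numeric(T))
  check_antoine_domain(params, T)
  if (warn_extrapolation) warn_if_extrapolating(params, T)
  log(10) * params$B * R_GAS * T^2 / (T + params$C)^2 / 1000
}

#' Vapour-pressure sensitivity to a temperature error
#'
#' Relative change in vapour pressure produced by a `dT` kelvin error in
#' temperature, the dominant uncertainty when boiling onsets are read to
#' about +/- 1 K. The canonical definition is the symmetric central
#' difference `100 (P(T+dT) - P(T-dT)) / (2 P(T))`; one-sided variants are
#' available for comparison studies.
#'
#' @inheritParams vapour_pressure
#' @param dT temperature perturbation in kelvin (default 1).
#' @param direction `"central"` (default), `"up"` (forward difference) or
#'   `"down"` (backward difference).
#' @return percent change in vapour pressure.
#' @export
vp_sensitivity <- function(params, T, dT = 1,
                           direction = c("central", "up", "down"),
                           warn_extrapolation = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(params, "antoine_params"), is.numeric(T), dT > 0)
  check_antoine_domain(params, c(T - dT, T, T + dT))
  p0 <- vapour_pressure(params, T, warn_extrapolation = warn_extrapolation)
  switch(direction,
    central = {
      up <- vapour_pressure(params, T + dT, warn_extrapolation = FALSE)
      dn <- vapour_pressure(params, T - dT, warn_extrapolation = FALSE)
      100 * (up - dn) / (2 * p0)
    },
    up = 100 * (vapour_pressure(params, T + dT, warn_extrapolation = FALSE) - p0) / p0,
    down = 100 * (p0 - vapour_pressure(params, T - dT, warn_extrapolation = FALSE)) / p0)
}

#' Vapour pressure relative to a reference compound
#'
#' Ratio of two Antoine laws evaluated at a common temperature, e.g. the
#' volatility of an analog relative to raspberry ketone at 298.15 K.
#'
#' @inheritParams vapour_pressure
#' @param reference an [antoine_params()] object for the reference compound.
#' @return dimensionless pressure ratio.
#' @export
relative_vp <- function(params, reference, T, warn_extrapolation = FALSE) {
  stopifnot(inherits(reference, "antoine_params"))
  p_ref <- vapour_pressure(reference, T, warn_extrapolation = warn_extrapolation)
  if (any(p_ref == 0))
    lv_stop("reference vapour pressure is zero", "lurevp_domain_error")
  vapour_pressure(params, T, warn_extrapolation = warn_extrapolation) / p_ref
}

#' Mean absolute percent deviation of observed pressures from an Antoine law
#'
#' `mean(|P_obs - P_calc| / P_calc) * 100` over a set of boiling
#' observations, the figure of merit quoted per compound for the DSC data.
#'
#' @param observed a data frame with columns `T` (kelvin) and `P_kPa`.
#' @param params an [antoine_params()] object.
#' @return mean absolute percent deviation.
#' @export
percent_deviation <- function(observed, params) {
  observed <- as_vapour_points(observed)
  if (nrow(observed) < 1L)
    lv_stop("need at least one observation", "lurevp_insufficient_data")
  p_calc <- vapour_pressure(params, observed$T, warn_extrapolation = FALSE)
  mean(abs(observed$P_kPa - p_calc) / p_calc) * 100
}

## normalise (T, P) input: data.frame with columns T and P_kPa, all positive
as_vapour_points <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("T", "P_kPa") %in% names(points)))
    lv_stop("boiling observations need columns 'T' and 'P_kPa'",
            "lurevp_parameter_error")
  if (any(!is.finite(points$T)) || any(!is.finite(points$P_kPa)) ||
      any(points$T <= 0) || any(points$P_kPa <= 0))
    lv_stop("temperatures and pressures must be positive and finite",
            "lurevp_domain_error")
  points
}

#' Fit the Antoine equation to boiling observations
#'
#' Least-squares fit of `log10(P) = A - B/(T + C)` to isothermal boiling
#' points, minimising the sum of squared residuals in `log10 P`. For a
#' fixed offset `C` the law is linear in `A` and `B`, so the fit profiles
#' the objective over `C` (one-dimensional search seeded from the
#' Clausius-Clapeyron line `C = 0`, then refined by golden-section /
#' parabolic interpolation) with an exact linear solve inside. The
#' constraint `min(T) + C > 1` K keeps the denominator away from zero.
#'
#' @param points data frame of boiling observations with columns `T`
#'   (kelvin) and `P_kPa`; at least 3 points.
#' @param init optional [antoine_params()] used to centre the search for
#'   `C`; by default the search starts from the Clausius-Clapeyron line
#'   (`C = 0`).
#' @param c_halfwidth half-width in kelvin of the coarse search window for
#'   `C` around its start value (default 500).
#' @param tol relative convergence tolerance on the profiled objective
#'   (default 1e-12).
#' @param max_iter maximum refinement evaluations (default 1e4).
#' @param compound optional label stored in the fitted parameters.
#'
#' @return An object of class `"antoine_fit"`: a list with elements
#'   `params` (an [antoine_params()] whose validity range is the data
#'   range), `sse_logP`, `mean_abs_pct_dev` (percent) and `converged`.
#' @examples
#' cl <- antoine_params(9.32104, 4291.92, -0.998176, 498.0, 587.4, "CL")
#' pts <- simulate_boiling_series(cl, c(5, 10, 20, 50, 100), noise_sd = 0)
#' fit_antoine(pts)
#' @export
fit_antoine <- function(points, init = NULL, c_halfwidth = 500,
                        tol = 1e-12, max_iter = 1e4, compound = NULL) {
  points <- as_vapour_points(points)
  if (nrow(points) < 3L)
    lv_stop("Antoine fitting needs at least 3 boiling points",
            "lurevp_insufficient_data")
  T <- points$T
  y <- log10(points$P_kPa)
  c_min <- 1 - min(T)                 # enforce min(T) + C > 1 K

  ## linear solve for (A, B) at fixed C; returns residual sum of squares
  ab_at <- function(C) {
    x <- 1 / (T + C)
    fit <- stats::lm.fit(cbind(1, -x), y)
    list(A = fit$coefficients[[1L]], B = fit$coefficients[[2L]],
         sse = sum(fit$residuals^2))
  }
  sse_at <- function(C) ab_at(C)$sse

  c_start <- if (!is.null(init)) init$C else 0
  lo <- max(c_min + 1e-6, c_start - c_halfwidth)
  hi <- c_start + c_halfwidth

  ## coarse grid to bracket the minimum, then 1-D refinement
  grid <- seq(lo, hi, length.out = 201L)
  sses <- vapply(grid, sse_at, numeric(1))
  i <- which.min(sses)
  bl <- grid[max(1L, i - 1L)]
  bu <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(sse_at, lower = bl, upper = bu,
                         tol = max(.Machine$double.eps^0.5, tol))
  C_hat <- opt$minimum
  ab <- ab_at(C_hat)

  converged <- is.finite(ab$sse) && ab$B > 0
  if (!converged)
    lv_warn("Antoine fit did not converge to a physical parameter set",
            "lurevp_fit_warning")

  params <- antoine_params(ab$A, ab$B, C_hat, min(T), max(T),
                           compound = compound)
  structure(
    list(params = params,
         sse_logP = ab$sse,
         mean_abs_pct_dev = percent_deviation(points, params),
         converged = converged,
         n = nrow(points)),
    class = "antoine_fit")
}

#' @export
print.antoine_fit <- function(x, ...) {
  cat("Antoine fit on", x$n, "boiling points\n")
  print(x$params)
  cat(sprintf("  SSE(log10 P) = %.3e;  mean |dev| = %.3g %%;  converged: %s\n",
              x$sse_logP, x$mean_abs_pct_dev, x$converged))
  invisible(x)
}
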