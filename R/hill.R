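#' Four-parameter Hill dose-response curve
#'
#' Sigmoid relation between drug concentration and percent cell-growth
#' inhibition: `effect = bottom + (top - bottom) / (1 + (conc/ec50)^(-steepness))`.
#' `bottom` may be negative (fitted MTT curves can dip below zero growth
#' inhibition) and effects are deliberately not clamped to \[0, 100\].
#'
#' @param bottom Percent inhibition at zero concentration.
#' @param top Percent inhibition at saturating concentration; must exceed
#'   `bottom`.
#' @param steepness Dimensionless positive slope factor.
#' @param ec50 Concentration of half-maximal effect (ug/mL), positive.
#' @param label Optional curve label.
#' @return An object of class `hill_curve`.
#' @examples
#' hill_curve(bottom = -1.06, top = 70.12, steepness = 23.14, ec50 = 0.0026)
#' @export
hill_curve <- function(bottom, top, steepness, ec50, label = NULL) {
  if (!.is_num1(bottom)) .stopf("'bottom' must be a single finite number")
  if (!.is_num1(top)) .stopf("'top' must be a single finite number")
  if (top <= bottom) .stopf("'top' (%.4g) must exceed 'bottom' (%.4g)", top, bottom)
  .check_pos(steepness, "steepness")
  .check_pos(ec50, "ec50")
  structure(list(bottom = bottom, top = top, steepness = steepness,
                 ec50 = ec50,
                 label = if (is.null(label)) NA_character_ else as.character(label)),
            class = "hill_curve")
}

#' @export
print.hill_curve <- function(x, ...) {
  cat(sprintf("Hill curve%s: bottom = %.4g%%, top = %.4g%%, steepness = %.4g, EC50 = %.4g ug/mL\n",
              if (!is.na(x$label)) paste0(" [", x$label, "]") else "",
              x$bottom, x$top, x$steepness, x$ec50))
  invisible(x)
}

# Core vectorized evaluation; `bottom` may be a scalar or a vector matched
# to `conc` (time-varying bottom in the coupled combination model). The
# zero-concentration value is the analytic limit `bottom` (the negative
# exponent is singular at 0).
hill_eval <- function(conc, bottom, top, steepness, ec50) {
  f <- rep(Inf, length(conc))
  pos <- conc > 0
  f[pos] <- (conc[pos] / ec50)^(-steepness)
  bottom + (top - bottom) / (1 + f)
}

#' Percent effect from tissue concentration via the Hill relation
#'
#' @param tissue_conc Tissue concentration(s), ug/mL, non-negative
#'   (vectorized).
#' @param curve A [hill_curve()].
#' @return Percent cell-growth inhibition; `curve$bottom` at zero
#'   concentration (analytic limit).
#' @examples
#' cv <- hill_curve(34.33, 80.39, 4.30, 0.0016)
#' hill_effect(cv$ec50, cv)  # midpoint: (bottom + top) / 2
#' @export
hill_effect <- function(tissue_conc, curve) {
  stopifnot(inherits(curve, "hill_curve"))
  if (!is.numeric(tissue_conc) || any(!is.finite(tissue_conc)) || any(tissue_conc < 0))
    .stopf("'tissue_conc' must be finite and non-negative")
  hill_eval(tissue_conc, curve$bottom, curve$top, curve$steepness, curve$ec50)
}

#' Quadratic modulation of the Hill bottom by itraconazole
#'
#' In the combination models the only dose-response parameter that responds
#' to itraconazole is the curve floor: `Bottom(x) = a x^2 + b x + c`, with
#' `x` the itraconazole tissue concentration in ug/mL. The quadratic is
#' calibrated on a bounded concentration range; evaluation beyond it is
#' permitted but flagged with a warning.
#'
#' @param a,b,c Quadratic coefficients (percent inhibition vs ug/mL).
#' @param calibration_range Two-element `c(0, x_max)` range (ug/mL) over
#'   which the coefficients were calibrated.
#' @param label Optional label.
#' @return An object of class `bottom_modulation`.
#' @examples
#' bottom_modulation(2.44, -1.95, -1.06)
#' @export
bottom_modulation <- function(a, b, c, calibration_range = c(0, 4.23384),
                              label = NULL) {
  for (nm in c("a", "b", "c")) {
    v <- get(nm)
    if (!.is_num1(v)) .stopf("'%s' must be a single finite number", nm)
  }
  if (length(calibration_range) != 2L || calibration_range[1] != 0 ||
      calibration_range[2] <= 0)
    .stopf("'calibration_range' must be c(0, x_max) with x_max > 0")
  structure(list(a = a, b = b, c = c,
                 calibration_range = as.numeric(calibration_range),
                 label = if (is.null(label)) NA_character_ else as.character(label)),
            class = "bottom_modulation")
}

#' @export
print.bottom_modulation <- function(x, ...) {
  cat(sprintf("Bottom(x) = %.4g x^2 + %.4g x + %.4g  (calibrated on x in [0, %.4g] ug/mL)\n",
              x$a, x$b, x$c, x$calibration_range[2]))
  invisible(x)
}

#' Evaluate the bottom-modulation quadratic
#'
#' @param x Itraconazole tissue concentration(s), ug/mL, non-negative
#'   (vectorized).
#' @param mod A [bottom_modulation()].
#' @param warn_extrapolation Warn (once per call) when any `x` exceeds the
#'   calibration range.
#' @return Bottom values (percent inhibition).
#' @examples
#' bottom_from_itraconazole(0, bottom_modulation(2.44, -1.95, -1.06))  # -1.06
#' @export
bottom_from_itraconazole <- function(x, mod, warn_extrapolation = TRUE) {
  stopifnot(inherits(mod, "bottom_modulation"))
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    .stopf("'x' must be finite and non-negative")
  if (warn_extrapolation && any(x > mod$calibration_range[2]))
    warning(sprintf("bottom modulation evaluated beyond its calibration range (max x = %.4g > %.4g ug/mL)",
                    max(x), mod$calibration_range[2]), call. = FALSE)
  mod$a * x^2 + mod$b * x + mod$c
}

#' Convert a molar concentration to a mass concentration
#'
#' MTT dose-response curves are commonly reported in micromolar while the
#' disposition model works in ug/mL; the conversion is
#' `ug/mL = uM * MW / 1000`.
#'
#' @param conc Concentration(s) in micromolar, non-negative.
#' @param molecular_weight Molecular weight (g/mol), positive. Itraconazole
#'   is 705.64 g/mol.
#' @return Concentration(s) in ug/mL.
#' @examples
#' micromolar_to_mass_conc(4, 705.64)  # 2.82256
#' @export
micromolar_to_mass_conc <- function(conc, molecular_weight) {
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0))
    .stopf("'conc' must be finite and non-negative")
  .check_pos(molecular_weight, "molecular_weight")
  conc * molecular_weight / 1000
}

#' Collapse diagnostic of the Hill denominator
#'
#' The power term `f(x) = (x/ec50)^(-steepness)` of the Hill equation. While
#' the tissue concentration stays far above `ec50`, `f` is negligible and the
#' effect sits at its plateau; once the concentration falls towards `ec50`,
#' `f` grows exponentially and the effect collapses abruptly. Takes explicit
#' constants (rather than a [hill_curve()]) so diagnostic parameterizations
#' can differ from the fitted averages.
#'
#' @param x Concentration(s), ug/mL, strictly positive (the power is
#'   singular at 0).
#' @param ec50 Half-maximal concentration (ug/mL).
#' @param steepness Positive slope factor.
#' @return `(x/ec50)^(-steepness)`; equals 1 at `x = ec50`.
#' @examples
#' collapse_diagnostic(0.008, 0.0019, 4.67)  # ~1.2e-3
#' @export
collapse_diagnostic <- function(x, ec50, steepness) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    .stopf("'x' must be strictly positive (the diagnostic is singular at 0)")
  .check_pos(ec50, "ec50")
  .check_pos(steepness, "steepness")
  (x / ec50)^(-steepness)
}
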