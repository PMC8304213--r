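#' Intravenous dose regimen
#'
#' Describes the forcing function of the disposition model: either an
#' instantaneous bolus into the central compartment or a constant-rate
#' infusion, optionally repeated at a fixed dosing interval.
#'
#' For an infusion, any two of `dose`, `rate` and `duration` may be given and
#' the third is derived; if all three are given they must satisfy
#' `rate * duration = dose` to relative tolerance 1e-9.
#'
#' @param route `"bolus"` or `"infusion"`.
#' @param dose Amount per administration (mg).
#' @param rate Infusion rate (mg/min, infusion only).
#' @param duration Infusion duration (min, infusion only).
#' @param start_time Start of the first administration (min).
#' @param n_doses Number of administrations (>= 1).
#' @param interval Time between dose starts (min); required when
#'   `n_doses > 1` and, for infusions, must be at least `duration`.
#'
#' @return An object of class `dose_regimen`.
#' @examples
#' dose_regimen("infusion", rate = 15.7, duration = 120)   # 1884 mg total
#' dose_regimen("bolus", dose = 900)
#' dose_regimen("infusion", dose = 100, duration = 60, n_doses = 3, interval = 1440)
#' @export
dose_regimen <- function(route = c("bolus", "infusion"), dose = NULL,
                         rate = NULL, duration = NULL, start_time = 0,
                         n_doses = 1L, interval = NULL) {
  route <- match.arg(route)
  .check_nonneg(start_time, "start_time")
  if (!.is_num1(n_doses) || n_doses < 1 || n_doses != round(n_doses))
    .stopf("'n_doses' must be a positive integer")
  n_doses <- as.integer(n_doses)

  if (route == "bolus") {
    if (is.null(dose)) .stopf("a bolus regimen requires 'dose'")
    .check_nonneg(dose, "dose")
    if (!is.null(rate) || !is.null(duration))
      .stopf("'rate'/'duration' only apply to infusion regimens")
  } else {
    given <- !c(dose = is.null(dose), rate = is.null(rate),
                duration = is.null(duration))
    if (sum(given) < 2) .stopf("an infusion regimen requires two of dose, rate, duration")
    if (is.null(dose)) dose <- rate * duration
    if (is.null(rate)) rate <- dose / duration
    if (is.null(duration)) duration <- dose / rate
    .check_nonneg(dose, "dose"); .check_nonneg(rate, "rate")
    .check_pos(duration, "duration")
    if (abs(rate * duration - dose) > 1e-9 * max(dose, 1))
      .stopf("inconsistent infusion: rate * duration = %.6g but dose = %.6g",
             rate * duration, dose)
  }

  if (n_doses > 1L) {
    if (is.null(interval)) .stopf("'interval' is required when n_doses > 1")
    .check_pos(interval, "interval")
    if (route == "infusion" && interval < duration - 1e-9)
      .stopf("dosing interval (%.6g min) is shorter than the infusion duration (%.6g min)",
             interval, duration)
  }

  structure(
    list(route = route, dose = dose,
         rate = if (route == "infusion") rate else NULL,
         duration = if (route == "infusion") duration else NULL,
         start_time = start_time, n_doses = n_doses, interval = interval),
    class = "dose_regimen"
  )
}

#' @export
print.dose_regimen <- function(x, ...) {
  if (x$route == "bolus") {
    cat(sprintf("IV bolus: %.6g mg at t = %.6g min", x$dose, x$start_time))
  } else {
    cat(sprintf("IV infusion: %.6g mg at %.6g mg/min over %.6g min from t = %.6g",
                x$dose, x$rate, x$duration, x$start_time))
  }
  if (x$n_doses > 1L)
    cat(sprintf(", repeated x%d every %.6g min", x$n_doses, x$interval))
  cat("\n")
  invisible(x)
}

# Start times of every administration (min).
dose_start_times <- function(regimen) {
  if (regimen$n_doses == 1L) regimen$start_time
  else regimen$start_time + (seq_len(regimen$n_doses) - 1) * regimen$interval
}

# Cumulative dose delivered by time t (mg); vectorized over t.
administered_by <- function(regimen, t) {
  starts <- dose_start_times(regimen)
  out <- numeric(length(t))
  for (s in starts) {
    if (regimen$route == "bolus") {
      out <- out + regimen$dose * (t >= s)
    } else {
      out <- out + regimen$rate * pmin(pmax(t - s, 0), regimen$duration)
    }
  }
  out
}

#' Simulation grid
#'
#' Fixed-step time grid and integration method for the disposition model.
#' The default step and method mirror the reference simulation settings
#' (fourth-order Runge-Kutta with h = 0.02 min).
#'
#' @param t_end Simulation length (min); must be an integer multiple of `h`
#'   (relative tolerance 1e-9).
#' @param h Step size (min).
#' @param method `"rk4"` or `"euler"`.
#' @return An object of class `simulation_grid` with `t_end`, `h`, `method`
#'   and `n_steps`.
#' @examples
#' simulation_grid(400)
#' simulation_grid(200, h = 0.05, method = "euler")
#' @export
simulation_grid <- function(t_end, h = 0.02, method = c("rk4", "euler")) {
  method <- match.arg(method)
  .check_pos(h, "h")
  .check_pos(t_end, "t_end")
  if (t_end < h) .stopf("'t_end' must be at least one step 'h'")
  n <- round(t_end / h)
  if (abs(n * h - t_end) > 1e-9 * t_end)
    .stopf("'t_end' (%g) must be an integer multiple of 'h' (%g)", t_end, h)
  structure(list(t_end = t_end, h = h, method = method, n_steps = as.integer(n)),
            class = "simulation_grid")
}

#' @export
print.simulation_grid <- function(x, ...) {
  cat(sprintf("Simulation grid: t_end = %g min, h = %g min, %s (%d steps)\n",
              x$t_end, x$h, toupper(x$method), x$n_steps))
  invisible(x)
}
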