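# Analytic biexponential solutions of the two-compartment model.
# These are the independent oracle for the fixed-step integrator and the
# model function for the concentration-time fitter.

# Unit-impulse response (amounts per mg of bolus at t = 0); vectorized in t.
# Returns list(A1, A2). Handles the repeated-root limit with t*exp(-lt).
impulse_amounts <- function(d, k21, k12, t) {
  l1 <- d$lambda1; l2 <- d$lambda2
  t <- pmax(t, 0)
  if ((l1 - l2) > 1e-12 * l1) {
    dl <- l1 - l2
    A1 <- ((l1 - k21) * exp(-l1 * t) + (k21 - l2) * exp(-l2 * t)) / dl
    A2 <- k12 * (exp(-l2 * t) - exp(-l1 * t)) / dl
  } else {
    l <- (l1 + l2) / 2
    A1 <- exp(-l * t) * (1 - (l - k21) * t)
    A2 <- k12 * t * exp(-l * t)
  }
  list(A1 = A1, A2 = A2)
}

# Integral of the impulse response from 0 to t (step response per unit rate).
step_amounts <- function(d, k21, k12, t) {
  l1 <- d$lambda1; l2 <- d$lambda2
  t <- pmax(t, 0)
  if ((l1 - l2) > 1e-12 * l1) {
    dl <- l1 - l2
    A1 <- ((l1 - k21) * (1 - exp(-l1 * t)) / l1 +
             (k21 - l2) * (1 - exp(-l2 * t)) / l2) / dl
    A2 <- k12 * ((1 - exp(-l2 * t)) / l2 - (1 - exp(-l1 * t)) / l1) / dl
  } else {
    l <- (l1 + l2) / 2
    e <- exp(-l * t)
    # int of e^{-lu}(1-(l-k21)u) and of k12 u e^{-lu}
    A1 <- (1 - e) / l - (l - k21) * (1 - e * (1 + l * t)) / l^2
    A2 <- k12 * (1 - e * (1 + l * t)) / l^2
  }
  list(A1 = A1, A2 = A2)
}

# Amounts (mg) in plasma and tissue at times t for a possibly repeated
# regimen, by superposition of time-shifted single-dose solutions.
closed_form_amounts <- function(params, regimen, t) {
  d <- derive_pk(params)
  A1 <- numeric(length(t)); A2 <- numeric(length(t))
  for (s in dose_start_times(regimen)) {
    u <- t - s
    on <- u > 0 | (regimen$route == "bolus" & u >= 0)
    if (!any(on)) next
    if (regimen$route == "bolus") {
      a <- impulse_amounts(d, params$k21, params$k12, u[on])
      A1[on] <- A1[on] + regimen$dose * a$A1
      A2[on] <- A2[on] + regimen$dose * a$A2
    } else {
      # constant input over [0, T]: A(t) = R [S(t) - S(t - T)], with the
      # step response S clamped to 0 for negative arguments
      a_full <- step_amounts(d, params$k21, params$k12, u[on])
      a_off <- step_amounts(d, params$k21, params$k12, pmax(u[on] - regimen$duration, 0))
      A1[on] <- A1[on] + regimen$rate * (a_full$A1 - a_off$A1)
      A2[on] <- A2[on] + regimen$rate * (a_full$A2 - a_off$A2)
    }
  }
  list(A1 = A1, A2 = A2)
}

#' Closed-form plasma concentration of the two-compartment model
#'
#' Analytic biexponential solution for a single IV bolus or constant-rate
#' infusion, used as the exact oracle for the fixed-step integrator and as
#' the model function in concentration-time fitting. For a bolus,
#' `C(t) = (Dose/Vd1) [ (lambda1-k21) e^(-lambda1 t) + (k21-lambda2)
#' e^(-lambda2 t) ] / (lambda1-lambda2) * 1000`; the infusion solution is the
#' corresponding convolution with a constant input over the infusion window.
#'
#' @param params A [pk_parameters()] object.
#' @param regimen A single-administration [dose_regimen()] (`n_doses == 1`).
#' @param t Times (min), vectorized; times before `start_time` return 0.
#' @return Plasma concentration (ug/mL) at `t`.
#' @examples
#' itz <- pk_parameters(8145.37, 82776.88, 228.45, 2.38e-2, 2.34e-3)
#' closed_form_concentration(itz, dose_regimen("infusion", dose = 100,
#'                                             duration = 60), 60)  # ~3.88
#' @export
closed_form_concentration <- function(params, regimen, t) {
  stopifnot(inherits(params, "pk_parameters"),
            inherits(regimen, "dose_regimen"))
  if (regimen$n_doses != 1L)
    .stopf("closed_form_concentration supports single-dose regimens only; use superposition for repeats")
  if (!is.numeric(t) || any(!is.finite(t)))
    .stopf("'t' must be finite numeric")
  closed_form_amounts(params, regimen, t)$A1 / params$Vd1 * 1000
}

# Closed-form plasma/tissue concentrations (ug/mL) for possibly repeated
# regimens, by superposition; internal (used by the multiple-dosing modes).
closed_form_concentrations_multi <- function(params, regimen, t) {
  a <- closed_form_amounts(params, regimen, t)
  list(plasma_conc = a$A1 / params$Vd1 * 1000,
       tissue_conc = a$A2 / params$Vd2 * 1000)
}
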