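#' Coupled two-drug combination scenario
#'
#' Pairs an anticancer drug (ACD) disposition model with an itraconazole
#' disposition model on a shared simulation grid. The two pharmacokinetic
#' systems never exchange mass (no disposition interaction is assumed);
#' the coupling is purely pharmacodynamic: at every time step the bottom of
#' the shared Hill curve is recomputed from the itraconazole tissue
#' concentration through a [bottom_modulation()] quadratic, and the percent
#' effect is evaluated at the ACD tissue concentration.
#'
#' @param acd_params,itz_params [pk_parameters()] for the ACD and
#'   itraconazole.
#' @param acd_regimen,itz_regimen [dose_regimen()] for each drug.
#' @param shared_curve A [hill_curve()] whose `top`, `steepness` and `ec50`
#'   are the averaged combination values; its `bottom` is replaced
#'   dynamically.
#' @param bottom_mod A [bottom_modulation()].
#' @param grid A [simulation_grid()] shared by both drugs.
#' @param label Scenario label.
#' @return An object of class `combination_scenario`.
#' @export
combination_scenario <- function(acd_params, acd_regimen, itz_params,
                                 itz_regimen, shared_curve, bottom_mod,
                                 grid, label = "combination") {
  stopifnot(inherits(acd_params, "pk_parameters"),
            inherits(itz_params, "pk_parameters"),
            inherits(acd_regimen, "dose_regimen"),
            inherits(itz_regimen, "dose_regimen"),
            inherits(shared_curve, "hill_curve"),
            inherits(bottom_mod, "bottom_modulation"),
            inherits(grid, "simulation_grid"))
  structure(list(acd_params = acd_params, acd_regimen = acd_regimen,
                 itz_params = itz_params, itz_regimen = itz_regimen,
                 shared_curve = shared_curve, bottom_mod = bottom_mod,
                 grid = grid, label = as.character(label)),
            class = "combination_scenario")
}

# Effect of an ACD trajectory under a (possibly time-varying) bottom taken
# from an itraconazole tissue-concentration series.
coupled_effect <- function(acd_traj, itz_tissue_conc, shared_curve, bottom_mod) {
  bottom_t <- bottom_from_itraconazole(itz_tissue_conc, bottom_mod,
                                       warn_extrapolation = FALSE)
  if (max(itz_tissue_conc) > bottom_mod$calibration_range[2])
    warning(sprintf("itraconazole tissue concentration (max %.4g ug/mL) exceeds the bottom-modulation calibration range [0, %.4g]",
                    max(itz_tissue_conc), bottom_mod$calibration_range[2]),
            call. = FALSE)
  effect_trajectory(acd_traj, shared_curve, bottom = bottom_t)
}

#' Simulate a coupled ACD + itraconazole combination
#'
#' Integrates both disposition models on the scenario grid and evaluates
#' the coupled effect-time curve: at each step
#' `bottom(t) = Bottom(itraconazole tissue conc)` and
#' `effect(t) = Hill(ACD tissue conc; bottom(t), top, steepness, ec50)`.
#'
#' @param scenario A [combination_scenario()].
#' @return A list of class `combination_run` with elements `acd` and `itz`
#'   (`disposition_trajectory`) and `effect` (`effect_trajectory`).
#' @examples
#' fx <- drug_fixtures()
#' sc <- combination_scenario(fx$params$gemcitabine, fx$regimens$gemcitabine,
#'                            fx$params$itraconazole,
#'                            fx$regimens$itraconazole_100,
#'                            fx$averaged_curves$gemcitabine,
#'                            fx$bottom_modulation$gemcitabine,
#'                            simulation_grid(400))
#' run <- simulate_combination(sc)
#' round(median(run$effect$effect[run$effect$times >= 30 &
#'                                run$effect$times <= 120]))  # plateau ~73
#' @export
simulate_combination <- function(scenario) {
  stopifnot(inherits(scenario, "combination_scenario"))
  acd <- integrate_disposition(scenario$acd_params, scenario$acd_regimen,
                               scenario$grid)
  itz <- integrate_disposition(scenario$itz_params, scenario$itz_regimen,
                               scenario$grid)
  eff <- coupled_effect(acd, itz$tissue_conc, scenario$shared_curve,
                        scenario$bottom_mod)
  structure(list(acd = acd, itz = itz, effect = eff,
                 label = scenario$label, scenario = scenario),
            class = "combination_run")
}

#' @export
print.combination_run <- function(x, ...) {
  cat(sprintf("Combination run '%s'\n", x$label))
  cat("  ACD: "); print(x$acd)
  cat("  Effect: "); print(x$effect)
  invisible(x)
}

#' Single-agent effect run with a fixed dose-response curve
#'
#' Convenience wrapper for the fixed-curve scenarios: one drug's disposition
#' mapped through one Hill curve with a constant bottom.
#'
#' @param params,regimen,grid Disposition inputs.
#' @param curve A [hill_curve()] (its own `bottom` is used, unmodulated).
#' @return An `effect_trajectory` (the disposition is attached as attribute
#'   `"disposition"`).
#' @export
single_agent_effect <- function(params, regimen, curve, grid) {
  traj <- integrate_disposition(params, regimen, grid)
  eff <- effect_trajectory(traj, curve)
  attr(eff, "disposition") <- traj
  eff
}

#' Compare scenarios by AUC_effect
#'
#' Tabulates the area under the effect-time curve for a set of effect
#' trajectories sharing a grid, and the percent change of each relative to
#' a named control: `(AUC - AUC_control) / AUC_control * 100`.
#'
#' @param effects Named list of `effect_trajectory` objects (names are the
#'   scenario labels).
#' @param control_label Name of the control scenario.
#' @param window Optional integration window `c(t0, t1)` (min); AUC_effect
#'   ratios are window-sensitive, so the window used is recorded in the
#'   output attributes.
#' @return A data.frame with columns `label`, `auc_effect`, `pct_change`
#'   (0 for the control), ordered as given.
#' @export
compare_auc_effect <- function(effects, control_label, window = NULL) {
  if (!is.list(effects) || is.null(names(effects)) || any(names(effects) == ""))
    .stopf("'effects' must be a named list of effect trajectories")
  if (!control_label %in% names(effects))
    .stopf("control scenario '%s' is not among the supplied scenarios", control_label)
  for (e in effects)
    if (!inherits(e, "effect_trajectory"))
      .stopf("every element of 'effects' must be an effect_trajectory")
  n_pts <- vapply(effects, function(e) length(e$times), integer(1))
  if (length(unique(n_pts)) != 1L)
    .stopf("all scenarios must share the same simulation grid")
  aucs <- vapply(effects, auc_effect, numeric(1), window = window)
  ctrl <- aucs[[control_label]]
  out <- data.frame(label = names(effects),
                    auc_effect = unname(aucs),
                    pct_change = unname((aucs - ctrl) / ctrl * 100),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "control") <- control_label
  attr(out, "window") <- if (is.null(window)) c(0, effects[[1]]$times[n_pts[1]]) else window
  out
}

#' Multiple-dosing specification
#'
#' How to extend a combination scenario's itraconazole arm to repeated
#' administrations: direct integration of the repeated regimen
#' (`ode_repeat`), superposition of time-shifted closed-form single-dose
#' solutions (`superposition`, valid because the kinetics are linear), or a
#' steady-state approximation (`css_approximation`) that pins the plasma
#' concentration at `css` and lets the tissue compartment relax towards its
#' partition equilibrium.
#'
#' @param mode One of `"ode_repeat"`, `"superposition"`,
#'   `"css_approximation"`.
#' @param css Steady-state plasma concentration (ug/mL); required in
#'   `css_approximation` mode.
#' @param interval Dosing interval (min); required for the repeated-dose
#'   modes.
#' @param n_doses Number of doses; required for the repeated-dose modes.
#' @return An object of class `multiple_dosing_spec`.
#' @export
multiple_dosing_spec <- function(mode = c("ode_repeat", "superposition",
                                          "css_approximation"),
                                 css = NULL, interval = NULL, n_doses = NULL) {
  mode <- match.arg(mode)
  if (mode == "css_approximation") {
    if (is.null(css)) .stopf("css_approximation mode requires 'css'")
    .check_pos(css, "css")
  } else {
    if (is.null(n_doses)) .stopf("mode '%s' requires 'n_doses'", mode)
    if (!.is_num1(n_doses) || n_doses < 1 || n_doses != round(n_doses))
      .stopf("'n_doses' must be a positive integer")
    if (n_doses > 1) {
      if (is.null(interval)) .stopf("'interval' is required when n_doses > 1")
      .check_pos(interval, "interval")
    }
  }
  structure(list(mode = mode, css = css, interval = interval,
                 n_doses = if (is.null(n_doses)) NULL else as.integer(n_doses)),
            class = "multiple_dosing_spec")
}

#' Simulate a combination under repeated itraconazole dosing
#'
#' @param scenario A [combination_scenario()]; its `itz_regimen` supplies
#'   the per-dose route/amount, and its grid must cover the dosing horizon.
#' @param spec A [multiple_dosing_spec()].
#' @return A list of class `combination_run` with `acd`
#'   (`disposition_trajectory`), `itz` (a `disposition_trajectory` in
#'   `ode_repeat` mode, otherwise a list with `times`, `plasma_conc`,
#'   `tissue_conc`), `effect` and `mode`.
#' @export
simulate_multiple_dosing <- function(scenario, spec) {
  stopifnot(inherits(scenario, "combination_scenario"),
            inherits(spec, "multiple_dosing_spec"))
  grid <- scenario$grid
  acd <- integrate_disposition(scenario$acd_params, scenario$acd_regimen, grid)
  times <- acd$times
  base <- scenario$itz_regimen

  if (spec$mode == "ode_repeat") {
    reg <- dose_regimen(base$route, dose = base$dose,
                        duration = base$duration,
                        start_time = base$start_time,
                        n_doses = spec$n_doses, interval = spec$interval)
    itz <- integrate_disposition(scenario$itz_params, reg, grid)
    itz_tissue <- itz$tissue_conc
  } else if (spec$mode == "superposition") {
    reg <- dose_regimen(base$route, dose = base$dose,
                        duration = base$duration,
                        start_time = base$start_time,
                        n_doses = spec$n_doses, interval = spec$interval)
    cc <- closed_form_concentrations_multi(scenario$itz_params, reg, times)
    itz <- list(times = times, plasma_conc = cc$plasma_conc,
                tissue_conc = cc$tissue_conc)
    itz_tissue <- cc$tissue_conc
  } else {
    # plasma pinned at css; tissue amount relaxes to its partition
    # equilibrium A2ss = k12 * css * Vd1 / (1000 * k21) with rate k21
    p <- scenario$itz_params
    a2ss <- p$k12 * spec$css * p$Vd1 / (1000 * p$k21)
    a2 <- a2ss * (1 - exp(-p$k21 * times))
    itz <- list(times = times,
                plasma_conc = rep(spec$css, length(times)),
                tissue_conc = a2 / p$Vd2 * 1000)
    itz_tissue <- itz$tissue_conc
  }

  eff <- coupled_effect(acd, itz_tissue, scenario$shared_curve,
                        scenario$bottom_mod)
  structure(list(acd = acd, itz = itz, effect = eff,
                 label = scenario$label, scenario = scenario,
                 mode = spec$mode),
            class = "combination_run")
}
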