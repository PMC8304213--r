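# Pipeline entry points tying the stages together. Each takes a parsed
# configuration (see read_run_config()), writes time series as CSV and a
# summary as JSON into an output directory, and returns the summary
# invisibly. A thin command-line wrapper around these functions ships in
# inst/cli/combopkpd.R.

#' Run disposition simulations from a configuration
#'
#' For each scenario, integrates the disposition model, writes the full
#' trajectory (`<label>_disposition.csv`) and a summary
#' (`simulate_summary.json`) containing the simulated plasma AUC, the
#' closed-form `Dose/CL` reference, Cmax and its time, and the maximum
#' relative mass-balance error.
#'
#' @param config A list (or path to a JSON/YAML file) with a `scenarios`
#'   list; each scenario has `label`, `drug` (fixture name or parameter
#'   mapping), `regimen` (fixture name or mapping) and optionally `grid`.
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly.
#' @export
run_simulate <- function(config, out_dir = ".") {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$scenarios)) .stopf("config has no 'scenarios' entry")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- drug_fixtures()
  summaries <- list()
  for (sc in config$scenarios) {
    if (is.null(sc$label)) .stopf("every scenario needs a 'label'")
    params <- resolve_params(sc$drug, fx)
    regimen <- resolve_regimen(sc$regimen, fx)
    grid <- resolve_grid(sc$grid)
    traj <- integrate_disposition(params, regimen, grid)
    df <- as.data.frame(traj)
    write.csv(df, file.path(out_dir, paste0(sc$label, "_disposition.csv")),
              row.names = FALSE, quote = FALSE)
    total_dose <- regimen$dose * regimen$n_doses
    summaries[[sc$label]] <- list(
      label = sc$label,
      auc_plasma = traj$auc_plasma[length(traj$auc_plasma)],
      auc_reference_dose_over_cl = auc_infinity(params, total_dose),
      cmax = max(traj$plasma_conc),
      t_cmax = traj$times[which.max(traj$plasma_conc)],
      mass_balance_max_rel_err = mass_balance_error(traj),
      grid = list(t_end = grid$t_end, h = grid$h, method = grid$method))
  }
  out <- list(scenarios = summaries)
  write_report_json(out, file.path(out_dir, "simulate_summary.json"))
  invisible(out)
}

#' Run coupled combination scenarios and compare AUC_effect
#'
#' Builds one coupled ACD + itraconazole run per scenario, writes each
#' effect-time curve (`<label>_effect.csv`) and a comparison report
#' (`combo_summary.json`) with per-scenario AUC_effect, percent change
#' versus the control, the initial plateau level (median effect over the
#' plateau window) and the post-peak drop-onset time.
#'
#' @param config A list (or config file path) with `acd` (fixture name or
#'   mapping), `grid`, an optional `window` for the AUC comparison, a
#'   `plateau_window` (two times, min), a `drop_threshold` (ug/mL), and a
#'   `scenarios` list whose entries have `label` and an `itz_regimen`
#'   (fixture name, mapping, or `null` for the no-itraconazole control);
#'   `control` names the control scenario.
#' @param out_dir Output directory.
#' @return The summary list, invisibly.
#' @export
run_combo <- function(config, out_dir = ".") {
  if (is.character(config)) config <- read_run_config(config)
  for (key in c("acd", "scenarios", "control"))
    if (is.null(config[[key]])) .stopf("config has no '%s' entry", key)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- drug_fixtures()

  acd_name <- config$acd
  if (!is.character(acd_name) || !acd_name %in% c("gemcitabine", "fluorouracil"))
    .stopf("'acd' must be \"gemcitabine\" or \"fluorouracil\"")
  grid <- resolve_grid(config$grid,
                       default_t_end = if (acd_name == "gemcitabine") 400 else 200)
  acd_params <- fx$params[[acd_name]]
  acd_regimen <- fx$regimens[[acd_name]]
  curve <- fx$averaged_curves[[acd_name]]
  mod <- fx$bottom_modulation[[acd_name]]

  labels <- vapply(config$scenarios, function(s) s$label %||% "", character(1))
  if (!config$control %in% labels)
    .stopf("control scenario '%s' missing from the scenario list", config$control)

  effects <- list()
  details <- list()
  for (sc in config$scenarios) {
    if (is.null(sc$itz_regimen)) {
      # no-itraconazole control: constant bottom = quadratic at x = 0
      eff <- single_agent_effect(acd_params, acd_regimen, curve, grid)
      acd_traj <- attr(eff, "disposition")
    } else {
      scen <- combination_scenario(acd_params, acd_regimen,
                                   fx$params$itraconazole,
                                   resolve_regimen(sc$itz_regimen, fx),
                                   curve, mod, grid, label = sc$label)
      run <- simulate_combination(scen)
      eff <- run$effect
      acd_traj <- run$acd
    }
    effects[[sc$label]] <- eff
    pw <- config$plateau_window %||%
      (if (acd_name == "gemcitabine") c(30, 120) else c(5, 40))
    in_pw <- eff$times >= pw[1] & eff$times <= pw[2]
    thr <- config$drop_threshold %||%
      (if (acd_name == "gemcitabine") 0.008 else 0.5)
    details[[sc$label]] <- list(
      plateau_effect = median(eff$effect[in_pw]),
      plateau_window = pw,
      drop_onset_min = drop_onset_time(acd_traj, thr),
      drop_threshold = thr)
    write.csv(as.data.frame(eff),
              file.path(out_dir, paste0(sc$label, "_effect.csv")),
              row.names = FALSE, quote = FALSE)
  }

  window <- config$window %||% NULL
  comp <- compare_auc_effect(effects, config$control,
                             window = if (is.null(window)) NULL
                                      else as.numeric(unlist(window)))
  out <- list(acd = acd_name,
              control = config$control,
              window = as.numeric(attr(comp, "window")),
              comparison = lapply(seq_len(nrow(comp)), function(i)
                c(as.list(comp[i, ]), details[[comp$label[i]]])),
              grid = list(t_end = grid$t_end, h = grid$h, method = grid$method))
  write_report_json(out, file.path(out_dir, "combo_summary.json"))
  invisible(out)
}

#' Fit models to a data file
#'
#' Dispatches on `mode`: `"pk2c"` fits a two-compartment model to a
#' concentration-time CSV (`time_min, conc_ug_per_ml`), `"hill"` fits a
#' four-parameter Hill curve to a dose-response CSV
#' (`conc, inhibition[, replicate]`), and `"bottom"` interpolates the
#' bottom-modulation quadratic through a calibration CSV (`x, bottom`).
#'
#' @param data_path Input CSV.
#' @param mode `"pk2c"`, `"hill"` or `"bottom"`.
#' @param out_json Optional path for the JSON fit report.
#' @param regimen For `"pk2c"`: the [dose_regimen()] (or fixture name)
#'   under which the data were collected.
#' @param init For `"pk2c"`: initial [pk_parameters()] (or fixture name).
#' @param seed Seed for the multi-start optimizer.
#' @return The fit report list, invisibly.
#' @export
run_fit <- function(data_path, mode = c("pk2c", "hill", "bottom"),
                    out_json = NULL, regimen = NULL, init = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (!file.exists(data_path)) .stopf("data file not found: %s", data_path)
  fx <- drug_fixtures()
  if (mode == "pk2c") {
    samples <- read_cp_csv(data_path)
    if (is.null(regimen) || is.null(init))
      .stopf("mode 'pk2c' requires 'regimen' and 'init'")
    if (is.character(regimen)) regimen <- resolve_regimen(regimen, fx)
    if (is.character(init)) init <- resolve_params(init, fx)
    fit <- fit_two_compartment(samples, regimen, init, seed = seed)
    report <- list(mode = mode, n_obs = fit$n_obs, converged = fit$converged,
                   estimates = fit$estimates, cv_percent = fit$cv_percent,
                   rss = fit$rss, seed = seed)
  } else if (mode == "hill") {
    df <- read.csv(data_path)
    if (!all(c("conc", "inhibition") %in% names(df)))
      .stopf("hill mode needs columns 'conc' and 'inhibition'; missing: %s",
             paste(setdiff(c("conc", "inhibition"), names(df)), collapse = ", "))
    res <- fit_hill(df)
    report <- list(mode = mode, n_obs = res$fit$n_obs,
                   converged = res$fit$converged,
                   estimates = res$fit$estimates,
                   cv_percent = res$fit$cv_percent, rss = res$fit$rss)
  } else {
    df <- read.csv(data_path)
    if (!all(c("x", "bottom") %in% names(df)))
      .stopf("bottom mode needs columns 'x' and 'bottom'; missing: %s",
             paste(setdiff(c("x", "bottom"), names(df)), collapse = ", "))
    if (nrow(df) == 0L) .stopf("empty calibration file")
    mod <- fit_bottom_quadratic(df)
    report <- list(mode = mode, coefficients = list(a = mod$a, b = mod$b, c = mod$c),
                   calibration_range = mod$calibration_range)
  }
  if (!is.null(out_json)) write_report_json(report, out_json)
  invisible(report)
}
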