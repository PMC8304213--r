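#' Effect-time trajectory from a disposition run
#'
#' Maps the tissue concentration of a simulated disposition trajectory
#' through a Hill dose-response curve, pointwise in time, and accumulates
#' the running area under the effect-time curve (AUC_effect) with the
#' rectangle accumulator of [cumulative_auc()].
#'
#' @param disposition A `disposition_trajectory` from
#'   [integrate_disposition()].
#' @param curve A [hill_curve()].
#' @param bottom Optional vector of time-varying bottom values (one per time
#'   point) overriding `curve$bottom`; used by the coupled combination
#'   model. Scalar or same length as `disposition$times`.
#' @return An `effect_trajectory`: list with `times` (min), `effect`
#'   (percent inhibition), `auc_effect` (running, percent * min), and a
#'   `negative_effect` flag vector marking intervals where the effect dips
#'   below zero (effects are not clamped).
#' @examples
#' gem <- pk_parameters(68019.62, 444.79, 3771.20, 6.64e-4, 0.102)
#' traj <- integrate_disposition(gem, dose_regimen("infusion", rate = 15.7,
#'                                                 duration = 120),
#'                               simulation_grid(400))
#' eff <- effect_trajectory(traj, hill_curve(-1.06, 70.12, 23.14, 0.0026))
#' max(eff$effect)
#' @export
effect_trajectory <- function(disposition, curve, bottom = NULL) {
  stopifnot(inherits(disposition, "disposition_trajectory"),
            inherits(curve, "hill_curve"))
  n <- length(disposition$times)
  if (is.null(bottom)) bottom <- curve$bottom
  if (!(length(bottom) %in% c(1L, n)))
    .stopf("'bottom' must be a scalar or match the trajectory length (%d)", n)
  grid <- attr(disposition, "grid")
  eff <- hill_eval(disposition$tissue_conc, bottom, curve$top,
                   curve$steepness, curve$ec50)
  structure(
    list(times = disposition$times,
         effect = eff,
         auc_effect = cumulative_auc(eff, grid$h),
         negative_effect = eff < 0),
    class = "effect_trajectory",
    curve = curve, grid = grid
  )
}

#' @export
print.effect_trajectory <- function(x, ...) {
  cat(sprintf("Effect trajectory: %d points, effect in [%.4g, %.4g]%%, AUC_effect = %.6g %%*min\n",
              length(x$times), min(x$effect), max(x$effect),
              x$auc_effect[length(x$auc_effect)]))
  if (any(x$negative_effect))
    cat(sprintf("  note: effect is negative on %.3g%% of the grid (not clamped)\n",
                100 * mean(x$negative_effect)))
  invisible(x)
}

#' @export
as.data.frame.effect_trajectory <- function(x, ...) {
  data.frame(times = x$times, effect = x$effect, auc_effect = x$auc_effect)
}

#' Total AUC_effect over an integration window
#'
#' AUC_effect ratios between scenarios are strongly sensitive to the
#' integration window, so the window is always explicit.
#'
#' @param effect An `effect_trajectory`.
#' @param window Two-element time window (min); defaults to the full
#'   trajectory.
#' @return Area under the effect-time curve over the window (percent * min),
#'   by rectangle accumulation.
#' @export
auc_effect <- function(effect, window = NULL) {
  stopifnot(inherits(effect, "effect_trajectory"))
  if (is.null(window)) return(effect$auc_effect[length(effect$auc_effect)])
  if (length(window) != 2L || window[1] >= window[2])
    .stopf("'window' must be c(t0, t1) with t0 < t1")
  f <- function(t) approx(effect$times, effect$auc_effect, t, rule = 2)$y
  f(window[2]) - f(window[1])
}

#' Onset time of the post-peak effect collapse
#'
#' Earliest time after the tissue-concentration maximum at which the tissue
#' concentration falls below a threshold. Defined from the post-peak
#' crossing so an infusion's rising phase cannot trigger it.
#'
#' @param disposition A `disposition_trajectory`.
#' @param threshold Tissue concentration threshold (ug/mL), positive.
#' @return Crossing time (min), or `NA` if the concentration never falls
#'   below the threshold after its maximum.
#' @examples
#' fu <- pk_parameters(9265.14, 2791.84, 850.01, 3.21e-2, 0.107)
#' traj <- integrate_disposition(fu, dose_regimen("bolus", dose = 900),
#'                               simulation_grid(200))
#' drop_onset_time(traj, 0.5)
#' @export
drop_onset_time <- function(disposition, threshold) {
  stopifnot(inherits(disposition, "disposition_trajectory"))
  .check_pos(threshold, "threshold")
  i_max <- which.max(disposition$tissue_conc)
  below <- which(disposition$tissue_conc < threshold)
  below <- below[below > i_max]
  if (length(below) == 0L) return(NA_real_)
  disposition$times[below[1]]
}

#' Onset time of the effect's departure from its plateau
#'
#' Complementary diagnostic to [drop_onset_time()]: the earliest post-peak
#' time at which the effect has fallen below its plateau by a given fraction
#' of the curve's dynamic range (`top - bottom`). This locates where an
#' effect-time curve visibly leaves its flat initial segment, which can
#' differ from any fixed concentration threshold.
#'
#' @param effect An `effect_trajectory`.
#' @param fraction Fraction of the dynamic range (default 0.01).
#' @return Onset time (min), or `NA` if the effect never departs.
#' @export
effect_drop_onset <- function(effect, fraction = 0.01) {
  stopifnot(inherits(effect, "effect_trajectory"))
  .check_pos(fraction, "fraction")
  curve <- attr(effect, "curve")
  i_max <- which.max(effect$effect)
  cutoff <- effect$effect[i_max] - fraction * (curve$top - curve$bottom)
  below <- which(effect$effect < cutoff)
  below <- below[below > i_max]
  if (length(below) == 0L) return(NA_real_)
  effect$times[below[1]]
}
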