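#' Noise model for synthetic data generation
#'
#' Reproducible noise for emulated assay data. Multiplicative lognormal
#' noise (constant coefficient of variation) is the default for plasma
#' concentration profiles, as bioanalytical PK assays typically have
#' CV-constant error; additive Gaussian noise is the default for percent
#' inhibition from MTT plates.
#'
#' @param kind `"multiplicative_lognormal"` or `"additive_gaussian"`.
#' @param sd Dispersion: the lognormal sigma (on the log scale) or the
#'   additive standard deviation (percentage points). `sd = 0` reproduces
#'   the model exactly.
#' @param seed Integer seed; identical seed and inputs give byte-identical
#'   output.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative_lognormal", "additive_gaussian"),
                        sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  .check_nonneg(sd, "sd")
  if (!.is_num1(seed) || seed != round(seed)) .stopf("'seed' must be an integer")
  structure(list(kind = kind, sd = sd, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(values, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$sd == 0) return(values)
  set.seed(noise$seed)
  eps <- rnorm(length(values), 0, noise$sd)
  if (noise$kind == "multiplicative_lognormal") values * exp(eps)
  else values + eps
}

#' Generate a synthetic plasma concentration-time profile
#'
#' Samples the closed-form two-compartment solution at the requested times
#' and perturbs it with the noise model, emulating a literature-style
#' sparse sampling design around an IV regimen.
#'
#' @param params A [pk_parameters()] object (the generating truth).
#' @param regimen A single-administration [dose_regimen()].
#' @param sample_times Sampling times (min), non-empty.
#' @param noise A [noise_model()]; `sd = 0` returns the noise-free curve.
#' @return A data.frame with columns `time` and `conc` (ug/mL).
#' @examples
#' gem <- pk_parameters(68019.62, 444.79, 3771.20, 6.64e-4, 0.102)
#' generate_cp_profile(gem, dose_regimen("infusion", rate = 15.7, duration = 120),
#'                     c(10, 30, 60, 120, 150, 210),
#'                     noise_model(sd = 0.05, seed = 1))
#' @export
generate_cp_profile <- function(params, regimen, sample_times,
                                noise = noise_model()) {
  if (length(sample_times) == 0L) .stopf("'sample_times' must be non-empty")
  if (any(sample_times < 0)) .stopf("'sample_times' must be non-negative")
  conc <- closed_form_concentration(params, regimen, sample_times)
  data.frame(time = sample_times, conc = apply_noise(conc, noise))
}

#' Generate synthetic MTT-style dose-response replicates
#'
#' Evaluates a Hill curve at a concentration panel and adds per-replicate
#' noise, emulating independent MTT experiments.
#'
#' @param curve A [hill_curve()] (the generating truth).
#' @param concentrations Concentration panel (same units as the curve's
#'   EC50), non-empty; a zero concentration responds at `bottom`.
#' @param replicates Number of replicates (>= 1).
#' @param noise A [noise_model()]; the additive Gaussian kind matches
#'   percent-inhibition data.
#' @return A data.frame with columns `conc`, `inhibition`, `replicate`.
#' @export
generate_dose_response <- function(curve, concentrations, replicates = 3,
                                   noise = noise_model("additive_gaussian")) {
  stopifnot(inherits(curve, "hill_curve"))
  if (length(concentrations) == 0L) .stopf("'concentrations' must be non-empty")
  if (any(concentrations < 0)) .stopf("'concentrations' must be non-negative")
  if (!.is_num1(replicates) || replicates < 1 || replicates != round(replicates))
    .stopf("'replicates' must be a positive integer")
  conc <- rep(concentrations, times = replicates)
  truth <- hill_effect(conc, curve)
  data.frame(conc = conc,
             inhibition = apply_noise(truth, noise),
             replicate = rep(seq_len(replicates), each = length(concentrations)))
}
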