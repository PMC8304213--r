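#' Bundled reference parameter sets
#'
#' Loads the reference inputs shipped with the package: the two-compartment
#' PK parameter sets for gemcitabine, 5-fluorouracil and itraconazole
#' (fitted from literature human plasma concentration-time profiles), the
#' eight combination dose-response (Hill) curves fitted from MTT assays in
#' the A549 lung-carcinoma line, the bottom-modulation quadratics, the
#' averaging exclusion rules, and the dose regimens of the reference
#' simulations.
#'
#' @param rounded_rates If `TRUE`, the itraconazole infusion regimens use
#'   the rounded rates (1.7, 5, 8.3 mg/min) instead of the exact
#'   dose/duration values (100/60, 300/60, 500/60 mg/min).
#' @return A list with components:
#' \describe{
#'   \item{params}{Named list of [pk_parameters()]: `gemcitabine`,
#'     `fluorouracil`, `itraconazole`.}
#'   \item{regimens}{Named list of [dose_regimen()]: `gemcitabine` (15.7
#'     mg/min x 120 min), `fluorouracil` (900 mg bolus),
#'     `itraconazole_100/300/500` (60-min infusions).}
#'   \item{hill_tables}{Named list of data.frames (columns `label`,
#'     `bottom`, `top`, `steepness`, `ec50`), one row per itraconazole
#'     co-incubation level I0/I2/I4/I6 (uM).}
#'   \item{hill_curves}{Named list of lists of [hill_curve()] objects, by
#'     ACD then level.}
#'   \item{bottom_modulation}{Named list of [bottom_modulation()].}
#'   \item{averaged_curves}{Named list of [hill_curve()] with the
#'     exclusion-honoring averaged top/steepness/ec50 and the quadratic's
#'     zero-concentration bottom.}
#'   \item{averaging_exclusions}{The per-parameter exclusion rules.}
#'   \item{itraconazole_mw}{705.64 g/mol.}
#'   \item{calibration_points}{Per ACD, the three (x, bottom) pairs (x in
#'     ug/mL) through which the quadratic interpolates.}
#' }
#' @examples
#' fx <- drug_fixtures()
#' fx$params$gemcitabine$CL            # 3771.20
#' fx$averaged_curves$gemcitabine$top  # 72.7625
#' @export
drug_fixtures <- function(rounded_rates = FALSE) {
  ext <- function(f) system.file("extdata", f, package = "combopkpd",
                                 mustWork = TRUE)
  pkj <- jsonlite::read_json(ext("reference_pk_parameters.json"),
                             simplifyVector = TRUE)
  mcj <- jsonlite::read_json(ext("reference_model_constants.json"),
                             simplifyVector = TRUE)
  hills <- read.csv(ext("reference_hill_curves.csv"), stringsAsFactors = FALSE)

  drugs <- c("gemcitabine", "fluorouracil", "itraconazole")
  params <- lapply(drugs, function(d) {
    p <- pkj[[d]]
    pk_parameters(p$Vd1, p$Vd2, p$CL, p$k12, p$k21, drug = d)
  })
  names(params) <- drugs

  rg <- mcj$regimens
  regimens <- list(
    gemcitabine = dose_regimen("infusion", rate = rg$gemcitabine$rate,
                               duration = rg$gemcitabine$duration),
    fluorouracil = dose_regimen("bolus", dose = rg$fluorouracil$dose)
  )
  for (nm in c("itraconazole_100", "itraconazole_300", "itraconazole_500")) {
    r <- rg[[nm]]
    regimens[[nm]] <-
      if (rounded_rates)
        dose_regimen("infusion", rate = rg$rounded_rates[[nm]],
                     duration = r$duration)
      else
        dose_regimen("infusion", dose = r$dose, duration = r$duration)
  }

  acds <- c("gemcitabine", "fluorouracil")
  hill_tables <- lapply(acds, function(d) {
    tab <- hills[hills$acd == d, c("label", "bottom", "top", "steepness", "ec50")]
    row.names(tab) <- NULL
    tab
  })
  names(hill_tables) <- acds

  hill_curves <- lapply(acds, function(d) {
    tab <- hill_tables[[d]]
    cv <- lapply(seq_len(nrow(tab)), function(i)
      hill_curve(tab$bottom[i], tab$top[i], tab$steepness[i], tab$ec50[i],
                 label = paste(d, tab$label[i])))
    names(cv) <- tab$label
    cv
  })
  names(hill_curves) <- acds

  mw <- mcj$itraconazole_molecular_weight
  x_cal <- micromolar_to_mass_conc(mcj$calibration_micromolar, mw)

  mods <- lapply(acds, function(d) {
    q <- mcj$bottom_modulation[[d]]
    bottom_modulation(q$a, q$b, q$c, calibration_range = c(0, max(x_cal)),
                      label = d)
  })
  names(mods) <- acds

  exclusions <- lapply(mcj$averaging_exclusions, as.list)

  averaged <- lapply(acds, function(d) {
    av <- average_hill_parameters(hill_tables[[d]],
                                  exclusions = exclusions[[d]])
    hill_curve(bottom = mods[[d]]$c, top = av$top,
               steepness = av$steepness, ec50 = av$ec50,
               label = paste(d, "averaged"))
  })
  names(averaged) <- acds

  calibration_points <- lapply(acds, function(d) {
    tab <- hill_tables[[d]]
    lev <- paste0("I", mcj$calibration_micromolar)
    data.frame(x = x_cal, bottom = tab$bottom[match(lev, tab$label)])
  })
  names(calibration_points) <- acds

  list(params = params, regimens = regimens,
       hill_tables = hill_tables, hill_curves = hill_curves,
       bottom_modulation = mods, averaged_curves = averaged,
       averaging_exclusions = exclusions,
       itraconazole_mw = mw, calibration_points = calibration_points)
}
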