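#' Two-compartment pharmacokinetic parameters
#'
#' Bundles the five constants of an amount-based, linear two-compartment
#' intravenous disposition model: drug enters the central (plasma)
#' compartment, exchanges with a peripheral (tissue) compartment through
#' first-order transfer, and is eliminated from the central compartment by
#' clearance. Internal units are fixed to mg, mL and min; concentrations are
#' reported in ug/mL.
#'
#' @param Vd1 Central volume of distribution (mL).
#' @param Vd2 Tissue volume of distribution (mL). Only rescales tissue
#'   concentration; it does not enter the plasma kinetics.
#' @param CL Clearance (mL/min).
#' @param k12 Central-to-tissue transfer rate constant (1/min).
#' @param k21 Tissue-to-central transfer rate constant (1/min).
#' @param drug Optional drug label.
#'
#' @return An object of class `pk_parameters`.
#' @examples
#' p <- pk_parameters(Vd1 = 68019.62, Vd2 = 444.79, CL = 3771.20,
#'                    k12 = 6.64e-4, k21 = 0.102, drug = "gemcitabine")
#' derive_pk(p)$k10
#' @export
pk_parameters <- function(Vd1, Vd2, CL, k12, k21, drug = NULL) {
  .check_pos(Vd1, "Vd1"); .check_pos(Vd2, "Vd2"); .check_pos(CL, "CL")
  .check_pos(k12, "k12"); .check_pos(k21, "k21")
  structure(
    list(Vd1 = Vd1, Vd2 = Vd2, CL = CL, k12 = k12, k21 = k21,
         drug = if (is.null(drug)) NA_character_ else as.character(drug)),
    class = "pk_parameters"
  )
}

#' @export
print.pk_parameters <- function(x, ...) {
  d <- derive_pk(x)
  cat("Two-compartment PK parameters",
      if (!is.na(x$drug)) paste0("(", x$drug, ")"), "\n")
  cat(sprintf("  Vd1 = %.4g mL   Vd2 = %.4g mL   CL = %.4g mL/min\n",
              x$Vd1, x$Vd2, x$CL))
  cat(sprintf("  k12 = %.4g /min k21 = %.4g /min\n", x$k12, x$k21))
  cat(sprintf("  derived: k10 = %.4g /min  Vss = %.4g mL  lambda = (%.4g, %.4g) /min\n",
              d$k10, d$Vss, d$lambda1, d$lambda2))
  invisible(x)
}

#' Derived disposition constants
#'
#' Computes the elimination rate constant `k10 = CL/Vd1`, the steady-state
#' volume `Vss = Vd1 + Vd2`, and the two hybrid disposition rate constants
#' `lambda1 >= lambda2`, the roots of the characteristic equation
#' `lambda^2 - (k10 + k12 + k21) lambda + k10 k21 = 0`.
#'
#' @param params A [pk_parameters()] object.
#' @return A list with `k10`, `Vss`, `lambda1`, `lambda2` and the terminal
#'   half-life `t_half_terminal = log(2)/lambda2` (min).
#' @examples
#' derive_pk(pk_parameters(9265.14, 2791.84, 850.01, 3.21e-2, 0.107))
#' @export
derive_pk <- function(params) {
  stopifnot(inherits(params, "pk_parameters"))
  k10 <- params$CL / params$Vd1
  s <- k10 + params$k12 + params$k21
  p <- k10 * params$k21
  disc <- s * s - 4 * p
  # two real positive roots are guaranteed for positive rate constants;
  # clamp tiny negative discriminants from rounding
  disc <- max(disc, 0)
  rt <- sqrt(disc)
  lambda1 <- (s + rt) / 2
  lambda2 <- (s - rt) / 2
  list(k10 = k10,
       Vss = params$Vd1 + params$Vd2,
       lambda1 = lambda1,
       lambda2 = lambda2,
       t_half_terminal = log(2) / lambda2)
}
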