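# Parameter recovery from data: nonlinear least-squares concentration-time
# fits (Levenberg-Marquardt via minpack.lm on log-scale parameters, which
# enforces positivity), four-parameter Hill fits of dose-response data, and
# the exact-interpolation quadratic relating the Hill bottom to
# itraconazole concentration.

# Numeric Jacobian (central differences) of a residual function at x.
num_jacobian <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    dx <- eps * max(abs(x[j]), 1e-8)
    xp <- x; xp[j] <- xp[j] + dx
    xm <- x; xm[j] <- xm[j] - dx
    J[, j] <- (fn(xp) - fn(xm)) / (2 * dx)
  }
  J
}

# Asymptotic CV% (100 * se / estimate) from the Jacobian of residuals with
# respect to the natural-scale parameters; pseudo-inverse guards against
# the near-singular information matrices of weakly identified constants.
asymptotic_cv <- function(resid_fn, estimates, n_obs) {
  p <- length(estimates)
  if (n_obs <= p) return(rep(NA_real_, p))
  J <- num_jacobian(resid_fn, estimates)
  rss <- sum(resid_fn(estimates)^2)
  s2 <- rss / (n_obs - p)
  jtj <- crossprod(J)
  sv <- svd(jtj)
  pos <- sv$d > max(sv$d) * 1e-12
  inv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  se <- sqrt(pmax(diag(s2 * inv), 0))
  100 * se / abs(estimates)
}

fit_result <- function(estimates, cv_percent, rss, converged, n_obs) {
  structure(list(estimates = estimates, cv_percent = cv_percent, rss = rss,
                 converged = converged, n_obs = n_obs),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s, n = %d, RSS = %.4g)\n",
              if (x$converged) "converged" else "NOT converged", x$n_obs, x$rss))
  if (x$converged) {
    tab <- data.frame(estimate = unlist(x$estimates),
                      cv_percent = unlist(x$cv_percent))
    print(signif(tab, 6))
  }
  invisible(x)
}

#' Fit a two-compartment model to concentration-time data
#'
#' Least-squares estimation of the disposition constants from plasma
#' concentration-time samples under a known dose regimen, using the
#' closed-form biexponential solution as the model function and
#' Levenberg-Marquardt minimization on log-scale parameters.
#'
#' Only four constants are structurally identifiable from plasma data
#' (`Vd1`, `CL`, `k12`, `k21`): the tissue volume never enters the plasma
#' kinetics of the amount-based model and is reported as the partition-
#' consistent value `Vd2 = Vd1 * k12 / k21`.
#'
#' @param samples A data.frame with columns `time` (min) and `conc` (ug/mL)
#'   and optionally `weight`; at least 5 distinct time points.
#' @param regimen The [dose_regimen()] under which the data were collected
#'   (single administration).
#' @param init A [pk_parameters()] initial guess.
#' @param n_starts Number of optimizer starts; starts beyond the first
#'   perturb `init` multiplicatively (deterministic given `seed`).
#' @param seed Seed for the extra starts.
#' @param weighting `"none"` (unweighted, default) or `"inverse_pred2"`
#'   (1/fitted^2 weights).
#' @return A `fit_result` whose `estimates` hold `Vd1`, `Vd2`, `CL`, `k12`,
#'   `k21` plus derived `k10`, `Vss`, `AUC` (for the regimen's dose) and
#'   `Cmax`; `cv_percent` holds asymptotic CVs for the four fitted
#'   constants. Also carries the fitted [pk_parameters()] as attribute
#'   `"params"`.
#' @export
fit_two_compartment <- function(samples, regimen, init, n_starts = 5,
                                seed = 1, weighting = c("none", "inverse_pred2")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(regimen, "dose_regimen"), inherits(init, "pk_parameters"))
  samples <- as.data.frame(samples)
  if (!all(c("time", "conc") %in% names(samples)))
    .stopf("'samples' needs columns 'time' and 'conc'")
  if (any(samples$time < 0) || any(samples$conc < 0))
    .stopf("times and concentrations must be non-negative")
  t_obs <- samples$time
  y_obs <- samples$conc
  if (length(unique(t_obs)) < 5L)
    .stopf("under-determined: at least 5 distinct time points are required")
  w <- if ("weight" %in% names(samples)) sqrt(samples$weight) else rep(1, length(y_obs))

  # validation-free model evaluation: the optimizer may probe extreme
  # parameter values mid-search, which must yield large residuals rather
  # than errors
  model_conc <- function(theta) {
    # theta = log(Vd1, CL, k12, k21)
    p <- exp(theta)
    if (any(!is.finite(p)) || any(p <= 0)) return(NULL)
    pk <- structure(list(Vd1 = p[1], Vd2 = p[1] * p[3] / p[4], CL = p[2],
                         k12 = p[3], k21 = p[4], drug = NA_character_),
                    class = "pk_parameters")
    pred <- closed_form_amounts(pk, regimen, t_obs)$A1 / pk$Vd1 * 1000
    if (any(!is.finite(pred))) return(NULL)
    pred
  }
  resid_fn <- function(theta) {
    pred <- model_conc(theta)
    if (is.null(pred)) return(rep(1e6, length(y_obs)))
    ww <- if (weighting == "inverse_pred2") 1 / pmax(pred, 1e-12) else w
    ww * (pred - y_obs)
  }

  theta0 <- log(c(init$Vd1, init$CL, init$k12, init$k21))
  starts <- list(theta0)
  if (n_starts > 1) {
    rs <- local({set.seed(seed); matrix(runif((n_starts - 1) * 4, log(0.5), log(2)), ncol = 4)})
    for (i in seq_len(n_starts - 1)) starts[[i + 1]] <- theta0 + rs[i, ]
  }

  best <- NULL
  for (th in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500,
                                                              ftol = 1e-14,
                                                              ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(fit_result(NULL, NULL, NA_real_, FALSE, length(y_obs)))

  # polish: restarting Levenberg-Marquardt at the optimum resets its trust
  # region, which escapes shallow stalls on weakly identified directions
  for (k in 1:2) {
    pol <- tryCatch(
      minpack.lm::nls.lm(par = best$fit$par, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500,
                                                              ftol = 1e-15,
                                                              ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(pol) && sum(pol$fvec^2) < best$rss)
      best <- list(fit = pol, rss = sum(pol$fvec^2))
  }

  p <- exp(best$fit$par)
  params <- pk_parameters(Vd1 = p[1], Vd2 = p[1] * p[3] / p[4], CL = p[2],
                          k12 = p[3], k21 = p[4])
  d <- derive_pk(params)
  nat_resid <- function(x) {
    pk <- structure(list(Vd1 = x[1], Vd2 = x[1] * x[3] / x[4], CL = x[2],
                         k12 = x[3], k21 = x[4], drug = NA_character_),
                    class = "pk_parameters")
    closed_form_amounts(pk, regimen, t_obs)$A1 / pk$Vd1 * 1000 - y_obs
  }
  cv <- asymptotic_cv(nat_resid, c(p[1], p[2], p[3], p[4]), length(y_obs))
  cmax <- if (regimen$route == "bolus") regimen$dose / params$Vd1 * 1000
          else closed_form_concentration(params, regimen,
                                         regimen$start_time + regimen$duration)
  res <- fit_result(
    estimates = list(Vd1 = params$Vd1, Vd2 = params$Vd2, CL = params$CL,
                     k12 = params$k12, k21 = params$k21,
                     k10 = d$k10, Vss = d$Vss,
                     AUC = auc_infinity(params, regimen$dose * regimen$n_doses),
                     Cmax = cmax),
    cv_percent = list(Vd1 = cv[1], CL = cv[2], k12 = cv[3], k21 = cv[4]),
    rss = best$rss, converged = TRUE, n_obs = length(y_obs))
  attr(res, "params") <- params
  res
}

#' Fit a four-parameter Hill curve to dose-response data
#'
#' Least-squares estimation of bottom, top, steepness and EC50 from percent
#' cell-growth-inhibition replicates, by Levenberg-Marquardt with steepness
#' and EC50 on the log scale.
#'
#' @param samples A data.frame with columns `conc` (same units as the
#'   desired EC50) and `inhibition` (percent); a `replicate` column is
#'   allowed and ignored by the fit. At least 4 distinct concentrations.
#' @return A list with `curve` (a [hill_curve()]) and `fit` (a
#'   `fit_result`; `cv_percent` are asymptotic per-parameter CVs).
#' @export
fit_hill <- function(samples) {
  samples <- as.data.frame(samples)
  if (!all(c("conc", "inhibition") %in% names(samples)))
    .stopf("'samples' needs columns 'conc' and 'inhibition'")
  if (any(samples$conc < 0)) .stopf("concentrations must be non-negative")
  x <- samples$conc
  y <- samples$inhibition
  if (length(unique(x)) < 4L)
    .stopf("under-determined: at least 4 distinct concentrations are required")
  if (sd(y) == 0)
    .stopf("degenerate data: all responses are identical")

  # start values: range of the response, EC50 near the mid-response conc
  ag <- tapply(y, x, mean)
  xs <- as.numeric(names(ag))
  b0 <- min(ag); t0 <- max(ag)
  mid <- (b0 + t0) / 2
  pos <- xs > 0
  e0 <- if (any(pos)) {
    i <- which.min(abs(ag[pos] - mid))
    max(xs[pos][i], min(xs[pos]))
  } else 1
  theta0 <- c(b0, t0, log(1), log(e0))

  resid_fn <- function(th) {
    hill_eval(x, th[1], th[2], exp(th[3]), exp(th[4])) - y
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500,
                                                            ftol = 1e-14,
                                                            ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9))
    return(list(curve = NULL,
                fit = fit_result(NULL, NULL, NA_real_, FALSE, length(y))))

  th <- fit$par
  est <- c(bottom = th[1], top = th[2], steepness = exp(th[3]), ec50 = exp(th[4]))
  nat_resid <- function(v) hill_eval(x, v[1], v[2], v[3], v[4]) - y
  cv <- asymptotic_cv(nat_resid, unname(est), length(y))
  curve <- hill_curve(est[["bottom"]], est[["top"]], est[["steepness"]],
                      est[["ec50"]])
  list(curve = curve,
       fit = fit_result(as.list(est),
                        list(bottom = cv[1], top = cv[2], steepness = cv[3],
                             ec50 = cv[4]),
                        sum(fit$fvec^2), TRUE, length(y)))
}

#' Calibrate the bottom-modulation quadratic
#'
#' Exact interpolation (3 points) or least squares (more points) of
#' `Bottom(x) = a x^2 + b x + c` through calibration pairs of itraconazole
#' tissue concentration and fitted Hill bottom.
#'
#' @param points A data.frame with columns `x` (ug/mL) and `bottom`
#'   (percent); `x` values must be distinct.
#' @param calibration_range Passed to [bottom_modulation()]; defaults to
#'   `c(0, max(x))`.
#' @return A [bottom_modulation()].
#' @examples
#' pts <- data.frame(x = c(0, 2.82256, 4.23384), bottom = c(-1.06, 12.83, 34.33))
#' fit_bottom_quadratic(pts)  # ~ (2.44, -1.95, -1.06)
#' @export
fit_bottom_quadratic <- function(points, calibration_range = NULL) {
  points <- as.data.frame(points)
  if (!all(c("x", "bottom") %in% names(points)))
    .stopf("'points' needs columns 'x' and 'bottom'")
  x <- points$x; y <- points$bottom
  if (anyDuplicated(x)) .stopf("duplicate x values make the quadratic ill-posed")
  if (length(x) < 3L) .stopf("at least 3 points are required")
  if (length(x) == 3L) {
    co <- solve(cbind(x^2, x, 1), y)
  } else {
    cf <- coef(lm(y ~ I(x^2) + x))   # (intercept, a, b)
    co <- c(cf[[2]], cf[[3]], cf[[1]])
  }
  if (is.null(calibration_range)) calibration_range <- c(0, max(x))
  bottom_modulation(unname(co[1]), unname(co[2]), unname(co[3]),
                    calibration_range = calibration_range)
}

#' Average Hill parameters across combination curves with exclusions
#'
#' Arithmetic means of `top`, `steepness` and `ec50` across a table of
#' fitted combination dose-response curves, honoring per-parameter row
#' exclusions (rows whose fitted value is unreliable are left out of that
#' parameter's mean). `bottom` is never averaged: in the coupled model it
#' becomes the concentration-dependent quadratic.
#'
#' @param rows A data.frame with columns `label`, `bottom`, `top`,
#'   `steepness`, `ec50`.
#' @param exclusions Named list mapping parameter name (`"top"`,
#'   `"steepness"`, `"ec50"`) to a character vector of row labels excluded
#'   from that parameter's mean.
#' @return A list with the averaged `top`, `steepness`, `ec50`.
#' @examples
#' tab <- data.frame(label = c("I6", "I4", "I2", "I0"),
#'                   bottom = c(34.33, 12.83, -5.51, -1.06),
#'                   top = c(80.39, 73.07, 67.47, 70.12),
#'                   steepness = c(4.30, 4.37, 5.35, 23.14),
#'                   ec50 = c(0.0016, 0.0018, 0.0022, 0.0026))
#' average_hill_parameters(tab, exclusions = list(steepness = "I0"))
#' @export
average_hill_parameters <- function(rows, exclusions = list()) {
  rows <- as.data.frame(rows)
  need <- c("label", "top", "steepness", "ec50")
  if (!all(need %in% names(rows)))
    .stopf("'rows' needs columns %s", paste(need, collapse = ", "))
  out <- list()
  for (par in c("top", "steepness", "ec50")) {
    keep <- !(rows$label %in% exclusions[[par]])
    if (!any(keep)) .stopf("all rows excluded for parameter '%s'", par)
    out[[par]] <- mean(rows[[par]][keep])
  }
  out
}
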