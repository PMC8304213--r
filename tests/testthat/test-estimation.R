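# Parameter recovery: concentration-time fits, Hill fits, the bottom
# quadratic, and averaging with exclusions.

test_that("noise-free concentration-time data are recovered to within 0.1%", {
  cases <- list(
    list(p = gem_params(), r = gem_regimen(), t = acd_sample_times()),
    list(p = fu_params(), r = fu_regimen(), t = acd_sample_times()),
    list(p = itz_params(), r = itz_regimen(100), t = itz_sample_times()))
  for (cs in cases) {
    prof <- generate_cp_profile(cs$p, cs$r, cs$t, noise_model(sd = 0))
    fit <- fit_two_compartment(prof, cs$r, cs$p)
    expect_true(fit$converged)
    for (nm in c("Vd1", "CL", "k12", "k21"))
      expect_lt(abs(fit$estimates[[nm]] - cs$p[[nm]]) / cs$p[[nm]], 1e-3)
    # tissue volume is reported at its partition-consistent value
    expect_equal(fit$estimates$Vd2,
                 fit$estimates$Vd1 * fit$estimates$k12 / fit$estimates$k21)
  }
})

test_that("5% multiplicative noise leaves CL and Vd1 within 10%", {
  gem <- gem_params()
  prof <- generate_cp_profile(gem, gem_regimen(), acd_sample_times(),
                              noise_model("multiplicative_lognormal", 0.05,
                                          seed = 1))
  fit <- fit_two_compartment(prof, gem_regimen(), gem)
  expect_lt(abs(fit$estimates$CL - gem$CL) / gem$CL, 0.10)
  expect_lt(abs(fit$estimates$Vd1 - gem$Vd1) / gem$Vd1, 0.10)
})

test_that("the concentration-time fit is initialization-robust", {
  for (cs in list(list(p = gem_params(), r = gem_regimen(), t = acd_sample_times()),
                  list(p = fu_params(), r = fu_regimen(), t = acd_sample_times()),
                  list(p = itz_params(), r = itz_regimen(100), t = itz_sample_times()))) {
    prof <- generate_cp_profile(cs$p, cs$r, cs$t, noise_model(sd = 0))
    set.seed(42)
    objs <- vapply(1:10, function(i) {
      f <- exp(runif(5, log(0.5), log(2)))
      init <- pk_parameters(cs$p$Vd1 * f[1], cs$p$Vd2 * f[2], cs$p$CL * f[3],
                            cs$p$k12 * f[4], cs$p$k21 * f[5])
      fit_two_compartment(prof, cs$r, init)$rss
    }, numeric(1))
    expect_lt(max(objs) - min(objs), 1e-6)
    expect_lt(max(objs), 1e-6)
  }
})

test_that("under-determined or degenerate inputs are rejected", {
  gem <- gem_params()
  two <- generate_cp_profile(gem, gem_regimen(), c(10, 60), noise_model(sd = 0))
  expect_error(fit_two_compartment(two, gem_regimen(), gem), "under-determined")
  flat <- data.frame(conc = c(0.1, 1, 10, 100), inhibition = rep(50, 4))
  expect_error(fit_hill(flat), "identical")
  expect_error(fit_hill(data.frame(conc = c(1, 2, 3), inhibition = c(1, 2, 3))),
               "4 distinct")
})

test_that("noise-free Hill data are recovered to within 0.1%", {
  truth <- hill_curve(12.83, 73.07, 4.37, 0.0018)
  concs <- exp(seq(log(1e-4), log(1), length.out = 8))
  dr <- generate_dose_response(truth, concs, replicates = 1,
                               noise_model("additive_gaussian", 0))
  res <- fit_hill(dr)
  expect_true(res$fit$converged)
  for (nm in c("bottom", "top", "steepness", "ec50"))
    expect_lt(abs(res$fit$estimates[[nm]] - truth[[nm]]) / abs(truth[[nm]]),
              1e-3)
})

test_that("noisy Hill replicates recover the top within 5 percentage points", {
  truth <- FX$hill_curves$fluorouracil$I4
  concs <- exp(seq(log(0.005), log(10), length.out = 8))
  dr <- generate_dose_response(truth, concs, replicates = 3,
                               noise_model("additive_gaussian", 3, seed = 7))
  res <- fit_hill(dr)
  expect_true(res$fit$converged)
  expect_lt(abs(res$fit$estimates$top - truth$top), 5)
})

test_that("three calibration points interpolate the bottom quadratic exactly", {
  for (acd in c("gemcitabine", "fluorouracil")) {
    pts <- FX$calibration_points[[acd]]
    mod <- fit_bottom_quadratic(pts)
    # exact interpolation through the inputs
    expect_lt(max(abs(bottom_from_itraconazole(pts$x, mod) - pts$bottom)),
              1e-9)
    # reproduces the reference coefficients to two decimals
    ref <- FX$bottom_modulation[[acd]]
    expect_equal(round(mod$a, 2), ref$a)
    expect_equal(round(mod$b, 2), ref$b)
    expect_equal(round(mod$c, 2), ref$c)
  }
  # collinear points give a vanishing quadratic term
  lin <- fit_bottom_quadratic(data.frame(x = c(0, 1, 2), bottom = c(1, 3, 5)))
  expect_equal(lin$a, 0)
  expect_error(fit_bottom_quadratic(data.frame(x = c(0, 0, 1),
                                               bottom = c(1, 2, 3))),
               "duplicate")
  # overdetermined least squares matches the interpolant on exact data
  pts4 <- data.frame(x = c(0, 1, 2, 3), bottom = 2 * c(0, 1, 2, 3)^2 - 1)
  mod4 <- fit_bottom_quadratic(pts4)
  expect_equal(c(mod4$a, mod4$b, mod4$c), c(2, 0, -1), tolerance = 1e-8)
})

test_that("averaging honors the per-parameter exclusion rules", {
  tab <- FX$hill_tables$gemcitabine
  av <- average_hill_parameters(tab, FX$averaging_exclusions$gemcitabine)
  expect_equal(round(av$top, 2), 72.76)
  expect_equal(round(av$steepness, 2), 4.67)
  expect_equal(round(av$ec50, 4), 0.0021)
  # forgetting the exclusion shifts the steepness mean to 9.29
  av_all <- average_hill_parameters(tab)
  expect_equal(round(av_all$steepness, 2), 9.29)
  # fluorouracil averages
  av5 <- average_hill_parameters(FX$hill_tables$fluorouracil,
                                 FX$averaging_exclusions$fluorouracil)
  expect_equal(round(av5$top, 2), 58.65)
  expect_equal(round(av5$steepness, 2), 2.39)
  expect_equal(round(av5$ec50, 2), 0.28)
  # single row passes through; excluding everything errors
  one <- tab[1, ]
  expect_equal(average_hill_parameters(one)$top, one$top)
  expect_error(average_hill_parameters(one, list(top = one$label)), "excluded")
})
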