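# Fixed-step integration vs the analytic biexponential oracle, AUC
# accounting, and trajectory invariants.

test_that("RK4 trajectories match the closed form to high accuracy", {
  cases <- list(
    list(p = gem_params(), r = gem_regimen(), t_end = 400),
    list(p = fu_params(), r = fu_regimen(), t_end = 200),
    list(p = itz_params(), r = itz_regimen(100), t_end = 400))
  for (cs in cases) {
    traj <- integrate_disposition(cs$p, cs$r, simulation_grid(cs$t_end))
    oracle <- closed_form_concentration(cs$p, cs$r, traj$times)
    rel <- abs(traj$plasma_conc[-1] - oracle[-1]) / oracle[-1]
    expect_lt(max(rel), 1e-6)
  }
})

test_that("Euler at h = 0.02 stays within 1e-3 of the closed form", {
  traj <- integrate_disposition(gem_params(), gem_regimen(),
                                simulation_grid(400, method = "euler"))
  oracle <- closed_form_concentration(gem_params(), gem_regimen(), traj$times)
  expect_lt(max(abs(traj$plasma_conc - oracle)) / max(oracle), 1e-3)
})

test_that("an independent adaptive ODE solver confirms the RK4 trajectory", {
  skip_if_not_installed("deSolve")
  gem <- gem_params()
  rhs <- function(t, y, parms) {
    r <- if (t < 120) 15.7 else 0
    el <- gem$CL / gem$Vd1 * y[1]
    list(c(r - gem$k12 * y[1] + gem$k21 * y[2] - el,
           gem$k12 * y[1] - gem$k21 * y[2]))
  }
  out <- deSolve::lsoda(c(0, 0), seq(0, 400, by = 10), rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  traj <- integrate_disposition(gem, gem_regimen(), simulation_grid(400))
  idx <- match(out[, 1], traj$times)
  expect_equal(traj$plasma_amount[idx], unname(out[, 2]), tolerance = 1e-6)
})

test_that("mass balance holds at every step for bolus and infusion", {
  for (cs in list(list(p = gem_params(), r = gem_regimen()),
                  list(p = fu_params(), r = fu_regimen()))) {
    traj <- integrate_disposition(cs$p, cs$r, simulation_grid(200))
    expect_lt(mass_balance_error(traj), 1e-6)
    expect_true(all(traj$plasma_amount >= 0))
    expect_true(all(traj$tissue_amount >= 0))
    # concentrations are amount/volume rescaled to ug/mL
    expect_equal(traj$plasma_conc, traj$plasma_amount / cs$p$Vd1 * 1000)
    expect_equal(traj$tissue_conc, traj$tissue_amount / cs$p$Vd2 * 1000)
    # eliminated amount and running AUC never decrease
    expect_true(all(diff(traj$eliminated_amount) >= 0))
    expect_true(all(diff(traj$auc_plasma) >= 0))
  }
})

test_that("peak concentrations match the reported values", {
  gem <- integrate_disposition(gem_params(), gem_regimen(), simulation_grid(400))
  expect_equal(max(gem$plasma_conc), 4.16, tolerance = 0.01)
  expect_equal(gem$times[which.max(gem$plasma_conc)], 120)
  fu <- integrate_disposition(fu_params(), fu_regimen(), simulation_grid(200))
  expect_equal(fu$plasma_conc[1], 97.14, tolerance = 1e-4)
  itz <- integrate_disposition(itz_params(), itz_regimen(100), simulation_grid(400))
  expect_equal(max(itz$plasma_conc), 3.88, tolerance = 0.01)
})

test_that("a zero dose yields an identically zero trajectory", {
  reg <- dose_regimen("bolus", dose = 0)
  traj <- integrate_disposition(gem_params(), reg, simulation_grid(10))
  expect_true(all(traj$plasma_amount == 0))
  expect_true(all(traj$auc_plasma == 0))
  expect_equal(mass_balance_error(traj), 0)
})

test_that("closed form: bolus starts at Dose/Vd1 and one-compartment limit decays with k10", {
  fu <- fu_params()
  expect_equal(closed_form_concentration(fu, fu_regimen(), 0),
               900 / fu$Vd1 * 1000)
  # negligible transfer: mono-exponential decay at k10
  p1 <- pk_parameters(Vd1 = 5000, Vd2 = 1000, CL = 250, k12 = 1e-12, k21 = 0.05)
  t <- c(1, 5, 20, 60)
  expect_equal(closed_form_concentration(p1, dose_regimen("bolus", dose = 100), t),
               100 / 5000 * 1000 * exp(-250 / 5000 * t), tolerance = 1e-8)
  expect_error(
    closed_form_concentration(gem_params(),
                              dose_regimen("bolus", dose = 1, n_doses = 2,
                                           interval = 60), 10),
    "single-dose")
})

test_that("repeated-root closed form stays finite and matches simulation", {
  # k10 = k21 with tiny k12 gives near-coincident roots
  p <- pk_parameters(Vd1 = 1000, Vd2 = 1000, CL = 100, k12 = 1e-13, k21 = 0.1)
  reg <- dose_regimen("bolus", dose = 50)
  traj <- integrate_disposition(p, reg, simulation_grid(60))
  oracle <- closed_form_concentration(p, reg, traj$times)
  expect_true(all(is.finite(oracle)))
  expect_lt(max(abs(traj$plasma_conc - oracle)) / max(oracle), 1e-6)
})

test_that("cumulative AUC accumulators behave as defined", {
  # constant series: rectangle accumulation is exact
  expect_equal(cumulative_auc(rep(2, 11), 1), seq(0, 20, by = 2))
  expect_equal(cumulative_auc(numeric(5), 0.5), rep(0, 5))
  # trapezoid on a linear ramp is exact
  ramp <- seq(0, 10, by = 1)
  expect_equal(cumulative_auc(ramp, 1, method = "trapezoid")[11], 50)
  expect_true(all(diff(cumulative_auc(ramp, 1)) >= 0))
})

test_that("simulated plasma AUC converges to Dose/CL", {
  cases <- list(
    list(p = gem_params(), r = gem_regimen(), dose = 1884, auc = 499.58),
    list(p = fu_params(), r = fu_regimen(), dose = 900, auc = 1058.81),
    list(p = itz_params(), r = itz_regimen(100), dose = 100, auc = 437.73))
  for (cs in cases) {
    expect_equal(auc_infinity(cs$p, cs$dose), cs$auc, tolerance = 1e-4)
    traj <- integrate_disposition(cs$p, cs$r,
                                  convergence_grid(cs$p, cs$r))
    sim_auc <- traj$auc_plasma[length(traj$auc_plasma)]
    expect_equal(sim_auc, auc_infinity(cs$p, cs$dose), tolerance = 5e-3)
  }
})

test_that("regimen validation catches inconsistent inputs", {
  expect_error(dose_regimen("infusion", dose = 100, rate = 2, duration = 60),
               "inconsistent")
  expect_error(dose_regimen("infusion", dose = 100, duration = 60,
                            n_doses = 2, interval = 30), "shorter")
  expect_error(dose_regimen("infusion", dose = 100), "two of")
  expect_error(dose_regimen("bolus", dose = 100, rate = 5), "infusion")
  expect_error(simulation_grid(100.013, h = 0.02), "integer multiple")
  # derived third quantity
  r <- dose_regimen("infusion", dose = 100, duration = 60)
  expect_equal(r$rate * r$duration, 100)
})
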