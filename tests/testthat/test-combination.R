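# Coupled two-drug scenarios, AUC_effect comparison, multiple dosing.

test_that("zero itraconazole dose reproduces the single-agent effect bit-for-bit", {
  grid <- simulation_grid(400)
  sc <- combination_scenario(gem_params(), gem_regimen(), itz_params(),
                             dose_regimen("infusion", dose = 0, duration = 60),
                             FX$averaged_curves$gemcitabine,
                             FX$bottom_modulation$gemcitabine, grid, "itz0")
  run <- simulate_combination(sc)
  single <- single_agent_effect(gem_params(), gem_regimen(),
                                FX$averaged_curves$gemcitabine, grid)
  expect_identical(run$effect$effect, single$effect)
  expect_identical(run$effect$auc_effect, single$auc_effect)
})

test_that("coupled runs plateau at the averaged top level", {
  rg <- simulate_combination(gem_combo_scenario(100))
  pe <- median(rg$effect$effect[rg$effect$times >= 30 & rg$effect$times <= 120])
  expect_equal(round(pe), 73)
  rf <- simulate_combination(fu_combo_scenario(100))
  pf <- median(rf$effect$effect[rf$effect$times >= 5 & rf$effect$times <= 40])
  expect_equal(round(pf), 59)
})

test_that("after the collapse the effect tracks the modulated bottom", {
  run <- simulate_combination(gem_combo_scenario(100))
  tail_idx <- run$effect$times >= 350
  bottoms <- bottom_from_itraconazole(run$itz$tissue_conc[tail_idx],
                                      FX$bottom_modulation$gemcitabine)
  expect_lt(max(abs(run$effect$effect[tail_idx] - bottoms)), 0.5)
})

test_that("AUC_effect is non-decreasing in the itraconazole dose", {
  aucs <- vapply(c(100, 300, 500), function(d)
    auc_effect(suppressWarnings(simulate_combination(gem_combo_scenario(d)))$effect),
    numeric(1))
  expect_true(all(diff(aucs) >= 0))
})

test_that("fixed-curve AUC_effect ordering follows the co-incubation level", {
  g400 <- simulation_grid(400)
  effs <- lapply(FX$hill_curves$gemcitabine, function(cv)
    single_agent_effect(gem_params(), gem_regimen(), cv, g400))
  cmp <- compare_auc_effect(effs, "I0")
  auc <- setNames(cmp$auc_effect, cmp$label)
  expect_true(auc[["I6"]] > auc[["I4"]] &&
                auc[["I4"]] > auc[["I0"]] &&
                auc[["I0"]] > auc[["I2"]])
  expect_equal(cmp$pct_change[cmp$label == "I0"], 0)

  g200 <- simulation_grid(200)
  effs5 <- lapply(FX$hill_curves$fluorouracil, function(cv)
    single_agent_effect(fu_params(), fu_regimen(), cv, g200))
  cmp5 <- compare_auc_effect(effs5, "I0")
  auc5 <- setNames(cmp5$auc_effect, cmp5$label)
  expect_true(auc5[["I6"]] > auc5[["I4"]] &&
                auc5[["I4"]] > auc5[["I0"]] &&
                auc5[["I0"]] > auc5[["I2"]])
})

test_that("comparison requires a control and identical grids", {
  g <- simulation_grid(100)
  e1 <- single_agent_effect(gem_params(), gem_regimen(),
                            FX$averaged_curves$gemcitabine, g)
  expect_error(compare_auc_effect(list(a = e1), "missing"), "control")
  # a scenario listed twice differs by 0%
  cmp <- compare_auc_effect(list(a = e1, b = e1), "a")
  expect_equal(cmp$pct_change, c(0, 0))
  e2 <- single_agent_effect(gem_params(), gem_regimen(),
                            FX$averaged_curves$gemcitabine,
                            simulation_grid(50))
  expect_error(compare_auc_effect(list(a = e1, b = e2), "a"), "grid")
})

test_that("multiple-dosing routes agree with each other", {
  grid <- simulation_grid(3000)
  sc <- gem_combo_scenario(100, grid = grid)
  ode <- simulate_multiple_dosing(sc, multiple_dosing_spec("ode_repeat",
                                                           n_doses = 3,
                                                           interval = 1440))
  sup <- simulate_multiple_dosing(sc, multiple_dosing_spec("superposition",
                                                           n_doses = 3,
                                                           interval = 1440))
  # linearity: summed time-shifted closed forms equal the direct ODE route
  expect_lt(max(abs(ode$itz$plasma_conc - sup$itz$plasma_conc)) /
              max(sup$itz$plasma_conc), 1e-6)
  expect_lt(max(abs(ode$itz$tissue_conc - sup$itz$tissue_conc)) /
              max(sup$itz$tissue_conc), 1e-6)
})

test_that("a single repeated dose reduces to the one-shot combination run", {
  sc <- gem_combo_scenario(100)
  one <- simulate_multiple_dosing(sc, multiple_dosing_spec("ode_repeat",
                                                           n_doses = 1))
  ref <- simulate_combination(sc)
  expect_identical(one$effect$effect, ref$effect$effect)
  expect_identical(one$itz$tissue_conc, ref$itz$tissue_conc)
})

test_that("the steady-state approximation relaxes to the partition limit", {
  p <- itz_params()
  grid <- simulation_grid(3000, h = 0.05)
  sc <- gem_combo_scenario(100, grid = grid)
  css <- 0.5
  run <- suppressWarnings(
    simulate_multiple_dosing(sc, multiple_dosing_spec("css_approximation",
                                                      css = css)))
  lim <- p$k12 * p$Vd1 / (p$k21 * p$Vd2) * css
  n <- length(run$itz$tissue_conc)
  expect_equal(run$itz$tissue_conc[n],
               lim * (1 - exp(-p$k21 * grid$t_end)), tolerance = 1e-6)
  expect_true(all(run$itz$plasma_conc == css))
  expect_error(simulate_multiple_dosing(sc, multiple_dosing_spec("css_approximation")),
               "css")
})
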