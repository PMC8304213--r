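# Shared fixtures for the test suite. The reference parameter sets are
# loaded once; small helpers build the recurring simulation objects.

FX <- drug_fixtures()

gem_params <- function() FX$params$gemcitabine
fu_params <- function() FX$params$fluorouracil
itz_params <- function() FX$params$itraconazole

gem_regimen <- function() FX$regimens$gemcitabine      # 15.7 mg/min x 120 min
fu_regimen <- function() FX$regimens$fluorouracil      # 900 mg bolus
itz_regimen <- function(dose = 100)
  FX$regimens[[paste0("itraconazole_", dose)]]         # dose mg over 60 min

# grid long enough for the plasma curve to be effectively eliminated
convergence_grid <- function(params, regimen, h = 0.02, n_half_lives = 25) {
  d <- derive_pk(params)
  t_inf <- if (regimen$route == "infusion") regimen$start_time + regimen$duration
           else regimen$start_time
  t_end <- ceiling((t_inf + n_half_lives * d$t_half_terminal) / h) * h
  simulation_grid(t_end, h = h)
}

gem_combo_scenario <- function(itz_dose = 100, grid = simulation_grid(400)) {
  combination_scenario(gem_params(), gem_regimen(), itz_params(),
                       itz_regimen(itz_dose),
                       FX$averaged_curves$gemcitabine,
                       FX$bottom_modulation$gemcitabine,
                       grid, label = paste0("gem+itz", itz_dose))
}

fu_combo_scenario <- function(itz_dose = 100, grid = simulation_grid(200)) {
  combination_scenario(fu_params(), fu_regimen(), itz_params(),
                       itz_regimen(itz_dose),
                       FX$averaged_curves$fluorouracil,
                       FX$bottom_modulation$fluorouracil,
                       grid, label = paste0("fu+itz", itz_dose))
}

# literature-style sparse sampling design (min) for ACD profiles
acd_sample_times <- function()
  c(5, 10, 20, 30, 45, 60, 90, 120, 125, 135, 150, 165, 180, 210)

itz_sample_times <- function()
  c(10, 30, 60, 90, 120, 240, 480, 960, 1440, 2160, 2880, 4320, 5760)
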