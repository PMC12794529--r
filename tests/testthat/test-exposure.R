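test_that("dose resolution applies the per-kg rule with absolute cap", {
  reg <- dose_regimen(dose_per_kg = 25)
  s <- txa_subjects(weight = c(58.2, 100), plt = 300, nirs = 65, il8 = 20)
  expect_equal(resolve_dose(reg, s), c(1455, 2000))
  expect_equal(resolve_dose(dose_regimen(amount = 2000), s), c(2000, 2000))
  expect_error(dose_regimen(dose_per_kg = 25, amount = 2000), "exactly one")
  expect_error(dose_regimen(dose_per_kg = 25, duration = 0), "positive")
})

test_that("closed-form infusion solution has the analytic limits", {
  ind <- individual_parameters(adult_median_subject())
  # zero at t = 0 and before the dose
  expect_equal(concentration_at(ind, 2000, 1, c(-5, 0)), c(0, 0))
  # near-instant infusion approaches the bolus limit dose/V1
  c0 <- concentration_at(ind, 2000, 1e-6, 1e-6)
  expect_equal(c0, 1000 * 2000 / ind$v1, tolerance = 1e-4)
  # continuity at the end of infusion
  eps <- 1e-9
  expect_equal(concentration_at(ind, 2000, 1, 1 - eps),
               concentration_at(ind, 2000, 1, 1 + eps), tolerance = 1e-6)
  # linear in dose
  t <- c(0.5, 1, 5, 60, 480)
  expect_equal(concentration_at(ind, 4000, 1, t),
               2 * concentration_at(ind, 2000, 1, t), tolerance = 1e-12)
})

test_that("closed-form solution matches the ODE oracle on random parameter sets", {
  sets <- random_parameter_sets(100, seed = 7)
  times <- c(0.25, 0.5, 1, 2, 5, 10, 30, 60, 120, 240, 480)
  for (i in seq_len(nrow(sets))) {
    ind <- sets[i, ]
    got <- concentration_at(ind, 1500, 1, times)
    ref <- ode_oracle(ind, 1500, 1, times)
    expect_equal(got, ref, tolerance = 1e-6)
  }
  # adult typical subject against the oracle on a 20-point grid
  ind <- individual_parameters(adult_median_subject())
  times <- seq(0.5, 480, length.out = 20)
  expect_equal(concentration_at(ind, 2000, 1, times),
               ode_oracle(ind, 2000, 1, times), tolerance = 1e-6)
})

test_that("closed-form total exposure equals dose/CL", {
  sets <- random_parameter_sets(1000, seed = 21)
  dose <- 1234
  auc <- vapply(seq_len(nrow(sets)), function(i)
    auc_inf_closed_form(sets[i, ], dose), numeric(1))
  expect_equal(auc, 1000 * dose / sets$cl, tolerance = 1e-9)
})

test_that("profiles superpose and respect the error mode", {
  s <- adult_median_subject()
  grid <- default_grid()
  # error off: observed equals true
  p0 <- simulate_profile(s, regimen = dose_regimen(amount = 2000),
                         grid = grid, error_mode = "none")
  expect_identical(p0$c_obs, p0$c_true)
  expect_equal(p0$c_true[1], 0)
  expect_true(all(p0$c_true >= 0))
  # two 1 g doses at t = 0 equal one 2 g dose
  p2 <- simulate_profile(s, regimen = dose_regimen(amount = 1000,
                                                   dose_times = c(0, 0)),
                         grid = grid, error_mode = "none")
  expect_equal(p2$c_true, p0$c_true, tolerance = 1e-12)
  # a second dose at 60 min superposes the time-shifted single-dose curve
  pm <- simulate_profile(s, regimen = dose_regimen(amount = 2000,
                                                   dose_times = c(0, 60)),
                         grid = grid, error_mode = "none")
  ind <- individual_parameters(s)
  shifted <- concentration_at(ind, 2000, 1, grid - 60)
  expect_equal(pm$c_true, p0$c_true + shifted, tolerance = 1e-12)
  # longer infusion never raises the true peak
  peaks <- vapply(c(1, 2, 5, 10, 30), function(d)
    max(simulate_profile(s, regimen = dose_regimen(amount = 2000, duration = d),
                         grid = grid, error_mode = "none")$c_true), numeric(1))
  expect_true(all(diff(peaks) <= 0))
})

test_that("proportional residual error has the model variance and is seeded", {
  p <- txa_pk_params()
  s <- adult_median_subject()
  grid <- seq(0, 480, by = 1)  # dense grid -> many error draws
  prof <- simulate_profile(s, p, dose_regimen(amount = 2000), grid,
                           error_mode = "proportional", seed = 17)
  keep <- prof$c_true > 0
  ratio <- prof$c_obs[keep] / prof$c_true[keep]
  expect_equal(sd(ratio), sqrt(0.0238), tolerance = 0.1)
  expect_true(all(prof$c_obs >= 0))
  # seeded reproducibility
  prof2 <- simulate_profile(s, p, dose_regimen(amount = 2000), grid,
                            error_mode = "proportional", seed = 17)
  expect_identical(prof, prof2)
})

test_that("cohort simulation is order-stable, seeded, and dose-linear", {
  subs <- generate_pediatric_population(n = 20, seed = 3)
  reg <- dose_regimen(dose_per_kg = 25)
  profs <- simulate_cohort(subs, regimen = reg, seed = 31)
  expect_length(profs, 20)
  expect_identical(vapply(profs, `[[`, character(1), "id"), subs$id)
  expect_identical(profs, simulate_cohort(subs, regimen = reg, seed = 31))
  # doubling the dose doubles every true concentration
  p1 <- simulate_cohort(subs, regimen = dose_regimen(dose_per_kg = 10),
                        error_mode = "none")
  p2 <- simulate_cohort(subs, regimen = dose_regimen(dose_per_kg = 20),
                        error_mode = "none")
  for (i in seq_along(p1))
    expect_equal(p2[[i]]$c_true, 2 * p1[[i]]$c_true, tolerance = 1e-12)
  # empty cohort -> empty result
  expect_length(simulate_cohort(subs[0, ], regimen = reg), 0)
})

test_that("profiles and NONMEM-style datasets round-trip as text", {
  subs <- generate_pediatric_population(n = 5, seed = 8)
  reg <- dose_regimen(dose_per_kg = 25)
  profs <- simulate_cohort(subs, regimen = reg, seed = 9)
  tf <- tempfile(fileext = ".tsv")
  write_profiles(profs, tf)
  back <- read_profiles(tf)
  expect_equal(length(back), length(profs))
  for (i in seq_along(profs)) {
    expect_equal(back[[i]]$c_true, profs[[i]]$c_true, tolerance = 1e-6)
    expect_equal(back[[i]]$id, profs[[i]]$id)
  }
  nm <- tempfile(fileext = ".tsv")
  export_nonmem(profs, subs, reg, nm)
  df <- read.table(nm, header = TRUE, sep = "\t", na.strings = ".")
  expect_equal(sort(unique(df$EVID)), c(0, 1))
  expect_equal(sum(df$EVID == 1), 5)           # one dose row per subject
  expect_equal(nrow(df), 5 * (1 + length(profs[[1]]$times)))
  expect_true(all(df$RATE[df$EVID == 1] ==
                  df$AMT[df$EVID == 1] / reg$duration))
})
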