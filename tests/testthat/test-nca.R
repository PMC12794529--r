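# hand-specified biexponential profile used as an analytic reference
make_biexp_profile <- function(A, B, alpha, beta, times) {
  conc <- A * exp(-alpha * times) + B * exp(-beta * times)
  structure(list(id = "x", times = times, c_true = conc, c_obs = conc,
                 dose_mg = NA_real_), class = "txa_profile")
}

biexp_auc <- function(A, B, alpha, beta, t_end) {
  A / alpha * (1 - exp(-alpha * t_end)) + B / beta * (1 - exp(-beta * t_end))
}

test_that("cmax returns the grid maximum with earliest-time tie-break", {
  p <- make_biexp_profile(80, 20, 0.02, 0.003, c(0, 1, 5, 30, 120, 480))
  cm <- nca_cmax(p)
  expect_equal(cm$cmax, 100)
  expect_equal(cm$tmax, 0)
  # all-zero profile
  z <- structure(list(id = "z", times = c(0, 10), c_true = c(0, 0),
                      c_obs = c(0, 0), dose_mg = 0), class = "txa_profile")
  expect_equal(nca_cmax(z), list(cmax = 0, tmax = 0))
  # tie between two equal maxima -> earliest time
  tie <- structure(list(id = "t", times = c(0, 5, 10), c_true = c(1, 7, 7),
                        c_obs = c(1, 7, 7), dose_mg = 1),
                   class = "txa_profile")
  expect_equal(nca_cmax(tie)$tmax, 5)
})

test_that("trapezoidal AUC matches constants and the analytic biexponential", {
  # constant concentration C over [0, T] integrates to C*T
  flat <- structure(list(id = "f", times = c(0, 60, 120, 240),
                         c_true = rep(7, 4), c_obs = rep(7, 4),
                         dose_mg = 1), class = "txa_profile")
  expect_equal(nca_auc(flat, 240), 7 * 240)
  # interpolated panel when t_end falls between grid points
  expect_equal(nca_auc(flat, 100), 7 * 100)
  expect_error(nca_auc(flat, 500), "horizon")
  # 1-min spacing: relative error against the closed form under 1%
  A <- 90; B <- 25; alpha <- 0.016; beta <- 0.0035
  p1 <- make_biexp_profile(A, B, alpha, beta, seq(0, 480, by = 1))
  ref <- biexp_auc(A, B, alpha, beta, 480)
  expect_lt(abs(nca_auc(p1, 480) - ref) / ref, 0.01)
})

test_that("trapezoidal AUC converges at second order to the closed form", {
  A <- 90; B <- 25; alpha <- 0.016; beta <- 0.0035
  ref <- biexp_auc(A, B, alpha, beta, 480)
  err <- vapply(c(4, 2, 1), function(h) {
    p <- make_biexp_profile(A, B, alpha, beta, seq(0, 480, by = h))
    abs(nca_auc(p, 480) - ref)
  }, numeric(1))
  # halving the spacing divides the error by about four
  expect_equal(err[1] / err[2], 4, tolerance = 0.1)
  expect_equal(err[2] / err[3], 4, tolerance = 0.1)
})

test_that("AUC windows are additive on a common grid", {
  s <- adult_median_subject()
  prof <- simulate_profile(s, regimen = dose_regimen(amount = 2000),
                           seed = 12)
  a4 <- nca_auc(prof, 240)
  a8 <- nca_auc(prof, 480)
  # panel-wise area over (240, 480]
  idx <- prof$times >= 240
  tt <- prof$times[idx]; cc <- prof$c_obs[idx]
  panel <- sum(diff(tt) * (cc[-1] + cc[-length(cc)]) / 2)
  expect_equal(a4 + panel, a8, tolerance = 1e-12)
  expect_lte(a4, a8)
})

test_that("time above threshold interpolates crossings linearly", {
  # two points (0, 20) -> (60, 5): crosses 10 at t = 40 min
  p <- structure(list(id = "a", times = c(0, 60), c_true = c(20, 5),
                      c_obs = c(20, 5), dose_mg = 1), class = "txa_profile")
  expect_equal(nca_time_above(p, 10), 40 / 60)
  # entirely below threshold
  lo <- structure(list(id = "b", times = c(0, 60), c_true = c(5, 1),
                       c_obs = c(5, 1), dose_mg = 1), class = "txa_profile")
  expect_equal(nca_time_above(lo, 10), 0)
  # multiple crossings accumulate
  w <- structure(list(id = "c", times = c(0, 10, 20, 30),
                      c_true = c(20, 5, 20, 5), c_obs = c(20, 5, 20, 5),
                      dose_mg = 1), class = "txa_profile")
  expect_equal(nca_time_above(w, 10), (20 / 3) * 3 / 60, tolerance = 1e-10)
})

test_that("noiseless adult typical time above 10 mg/L matches the root-finding oracle", {
  s <- adult_median_subject()
  prof <- simulate_profile(s, regimen = dose_regimen(amount = 2000),
                           error_mode = "none")
  got <- nca_time_above(prof, 10)
  # frozen: root of the closed-form biexponential computed independently
  expect_equal(got, 5.0263, tolerance = 0.01)
})

test_that("time above threshold is monotone in threshold and dose", {
  s <- adult_median_subject()
  doses <- c(500, 1000, 2000, 4000)
  profs <- lapply(doses, function(d)
    simulate_profile(s, regimen = dose_regimen(amount = d),
                     error_mode = "none"))
  ta_dose <- vapply(profs, nca_time_above, numeric(1), threshold = 10)
  expect_true(all(diff(ta_dose) >= 0))
  thresholds <- c(2, 5, 10, 20, 50)
  ta_thr <- vapply(thresholds, function(th)
    nca_time_above(profs[[3]], th), numeric(1))
  expect_true(all(diff(ta_thr) <= 0))
})

test_that("batch NCA preserves order and reports subject context on failure", {
  subs <- generate_pediatric_population(n = 10, seed = 4)
  profs <- simulate_cohort(subs, regimen = dose_regimen(dose_per_kg = 25),
                           seed = 5)
  m <- nca_batch(profs)
  expect_equal(nrow(m), 10)
  expect_equal(m$id, subs$id)
  expect_true(all(m$auc_0_4h <= m$auc_0_8h))
  expect_true(all(m[c("cmax", "auc_0_4h", "auc_0_8h", "t_above")] >= 0))
  expect_true(all(m$t_above <= 8))
  # permuting input permutes output identically
  perm <- c(3, 1, 2, 10, 4:9)
  m2 <- nca_batch(structure(profs[perm], class = "txa_profiles"))
  expect_equal(m2, m[perm, ], ignore_attr = TRUE)
  # AUC window beyond the horizon names the subject
  expect_error(nca_batch(profs, t_ends = c(auc = 1000)), "ped_0001")
})
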