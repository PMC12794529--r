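#' Closed-form concentration during and after a zero-order infusion
#'
#' Central-compartment concentration of the two-compartment model for a
#' single zero-order infusion starting at time 0.  During the infusion
#' the solution is the rising biexponential
#' \eqn{(R_0/V_1)\,[\,(A/\alpha)(1-e^{-\alpha t}) + (B/\beta)(1-e^{-\beta t})\,]};
#' after the infusion ends each term decays from its end-of-infusion
#' value.  The solution is continuous at the infusion end and linear in
#' dose.  Coalescing phases (`alpha == beta`) are handled upstream by
#' [disposition_constants()] via an epsilon split of the double root.
#'
#' @param ind individual parameters: a list/row with `cl`, `v1`, `q`,
#'   `v2` (mL/min and mL), or a precomputed `txa_disposition`.
#' @param dose_mg administered dose (mg).
#' @param duration infusion duration (min, > 0).
#' @param t vector of times since infusion start (min); values < 0
#'   return 0.
#' @return Concentrations in mg/L at each `t`.
#' @examples
#' ind <- list(cl = 162, v1 = 19796, q = 88.6, v2 = 13045)
#' concentration_at(ind, 2000, 1, c(0, 1, 60, 480))
#' @export
concentration_at <- function(ind, dose_mg, duration, t) {
  dc <- if (inherits(ind, "txa_disposition")) ind else disposition_constants(ind)
  stopifnot(dose_mg >= 0, duration > 0)
  r0 <- dose_mg / duration            # mg/min
  tt <- pmax(t, 0)
  te <- pmin(tt, duration)            # time infused so far
  tp <- pmax(tt - duration, 0)        # time since infusion end
  term <- function(coef, lam)
    (coef / lam) * (1 - exp(-lam * te)) * exp(-lam * tp)
  conc <- (r0 / dc$v1) *
    (term(dc$coef_a, dc$alpha) + term(dc$coef_b, dc$beta))
  conc[t < 0] <- 0
  1000 * conc                         # mg/mL -> mg/L
}

#' Closed-form AUC from time zero to infinity
#'
#' Analytic area under the true concentration curve for one infusion;
#' algebraically equal to `1000 * dose / CL` (mg*min/L) for any
#' two-compartment parameter set.  Used as the analytic reference for the
#' trapezoidal NCA.
#'
#' @inheritParams concentration_at
#' @return AUC in mg*min/L.
#' @export
auc_inf_closed_form <- function(ind, dose_mg) {
  dc <- if (inherits(ind, "txa_disposition")) ind else disposition_constants(ind)
  1000 * (dose_mg / dc$v1) * (dc$coef_a / dc$alpha + dc$coef_b / dc$beta)
}

#' Simulate a concentration-time profile for one subject
#'
#' Computes the true profile by superposing the closed-form infusion
#' solution over all dose times, then overlays proportional residual
#' error on the observed series: `c_obs = c_true * (1 + eps)` with
#' `eps ~ N(0, sigma2_prop)`, truncated below at zero.  With
#' `error_mode = "none"` the observed series equals the true series.
#'
#' @param subject one-row subject table (or one row of a larger table).
#' @param params a [txa_pk_params()] set.
#' @param regimen a [dose_regimen()].
#' @param grid sampling times (min), see [default_grid()].
#' @param error_mode `"proportional"` (default) or `"none"`.
#' @param seed integer seed for the residual-error draws, or `NULL`.
#' @return A list of class `txa_profile`: `id`, `times`, `c_true`,
#'   `c_obs` (mg/L), `dose_mg`.
#' @export
simulate_profile <- function(subject, params = txa_pk_params(),
                             regimen = dose_regimen(amount = 2000),
                             grid = default_grid(),
                             error_mode = c("proportional", "none"),
                             seed = NULL) {
  error_mode <- match.arg(error_mode)
  validate_grid(grid)
  subject <- subject[1, , drop = FALSE]
  ind <- individual_parameters(subject, params)
  dose <- resolve_dose(regimen, subject)
  dc <- disposition_constants(ind)
  c_true <- rep(0, length(grid))
  for (td in regimen$dose_times)
    c_true <- c_true + concentration_at(dc, dose, regimen$duration, grid - td)
  if (error_mode == "proportional" && params$sigma2_prop > 0) {
    if (!is.null(seed)) set.seed(seed)
    eps <- stats::rnorm(length(grid), 0, sqrt(params$sigma2_prop))
    c_obs <- pmax(c_true * (1 + eps), 0)
  } else {
    c_obs <- c_true
  }
  structure(list(id = subject$id, times = grid, c_true = c_true,
                 c_obs = c_obs, dose_mg = dose),
            class = "txa_profile")
}

#' Simulate concentration-time profiles for a cohort
#'
#' Maps the closed-form profile simulation over all subjects with
#' independent residual-error streams.  Output order follows input
#' order, and the result is reproducible for a given seed.
#'
#' @param subjects a subject table.
#' @param params a [txa_pk_params()] set.
#' @param regimen a [dose_regimen()].
#' @param grid sampling times (min).
#' @param error_mode `"proportional"` or `"none"`.
#' @param seed integer seed for all residual-error draws.
#' @return A list of `txa_profile` objects, class `txa_profiles`.
#' @export
simulate_cohort <- function(subjects, params = txa_pk_params(),
                            regimen = dose_regimen(amount = 2000),
                            grid = default_grid(),
                            error_mode = c("proportional", "none"),
                            seed = NULL) {
  error_mode <- match.arg(error_mode)
  validate_grid(grid)
  n <- nrow(subjects)
  if (n == 0L) return(structure(list(), class = "txa_profiles"))
  validate_subjects(subjects)
  ind <- individual_parameters(subjects, params)
  doses <- resolve_dose(regimen, subjects)
  with_noise <- error_mode == "proportional" && params$sigma2_prop > 0
  if (with_noise) {
    if (!is.null(seed)) set.seed(seed)
    eps <- matrix(stats::rnorm(n * length(grid), 0, sqrt(params$sigma2_prop)),
                  nrow = n, byrow = TRUE)
  }
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    dc <- disposition_constants(ind[i, ])
    c_true <- rep(0, length(grid))
    for (td in regimen$dose_times)
      c_true <- c_true + concentration_at(dc, doses[i], regimen$duration,
                                          grid - td)
    c_obs <- if (with_noise) pmax(c_true * (1 + eps[i, ]), 0) else c_true
    profiles[[i]] <- structure(
      list(id = subjects$id[i], times = grid, c_true = c_true,
           c_obs = c_obs, dose_mg = doses[i]),
      class = "txa_profile")
  }
  structure(profiles, class = "txa_profiles")
}

#' Export or import simulated profiles as delimited text
#'
#' Long format: one row per subject per time point, columns `id`,
#' `time`, `c_true`, `c_obs`, `dose_mg`.
#'
#' @param profiles a `txa_profiles` list from [simulate_cohort()].
#' @param path file path (tab-separated text).
#' @return `read_profiles()` returns a `txa_profiles` list;
#'   `write_profiles()` returns `path` invisibly.
#' @export
write_profiles <- function(profiles, path) {
  df <- profiles_to_df(profiles)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(id = "character"),
                          stringsAsFactors = FALSE)
  ids <- unique(df$id)
  profiles <- lapply(ids, function(i) {
    d <- df[df$id == i, ]
    structure(list(id = i, times = d$time, c_true = d$c_true,
                   c_obs = d$c_obs, dose_mg = d$dose_mg[1]),
              class = "txa_profile")
  })
  structure(profiles, class = "txa_profiles")
}

profiles_to_df <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(id = p$id, time = p$times, c_true = p$c_true,
               c_obs = p$c_obs, dose_mg = p$dose_mg,
               stringsAsFactors = FALSE)))
}

#' Export a cohort simulation as a NONMEM-style dataset
#'
#' Writes dose and observation records in the conventional pharmacometric
#' layout (columns `ID`, `TIME`, `AMT`, `RATE`, `DV`, `EVID`, `MDV` plus
#' the subject covariates) for cross-checking in external tools.  Dose
#' records carry the administered amount and zero-order infusion rate;
#' observation records carry the observed concentration.
#'
#' @param profiles a `txa_profiles` list.
#' @param subjects the subject table the profiles were simulated from.
#' @param regimen the [dose_regimen()] used.
#' @param path file path (tab-separated text).
#' @return `path`, invisibly.
#' @export
export_nonmem <- function(profiles, subjects, regimen, path) {
  validate_subjects(subjects)
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    s <- subjects[subjects$id == p$id, ][1, ]
    dose_rows <- data.frame(
      ID = i, TIME = regimen$dose_times, AMT = p$dose_mg,
      RATE = p$dose_mg / regimen$duration, DV = NA_real_,
      EVID = 1L, MDV = 1L,
      WT = s$weight, PLT = s$plt, NIRS = s$nirs, IL8 = s$il8)
    obs_rows <- data.frame(
      ID = i, TIME = p$times, AMT = NA_real_, RATE = NA_real_,
      DV = p$c_obs, EVID = 0L, MDV = 0L,
      WT = s$weight, PLT = s$plt, NIRS = s$nirs, IL8 = s$il8)
    out <- rbind(dose_rows, obs_rows)
    out[order(out$TIME, -out$EVID), ]
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = ".")
  invisible(path)
}
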