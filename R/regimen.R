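#' Define an intravenous TXA dose regimen
#'
#' A regimen is either weight-based (`dose_per_kg` with an absolute cap,
#' default 2 g/dose) or a fixed absolute amount (`amount`), administered
#' as a zero-order infusion of `duration` minutes at each time in
#' `dose_times`.  A "bolus" is operationalized as a 1-min infusion.
#'
#' @param dose_per_kg dose in mg/kg (weight-based rule); exclusive with
#'   `amount`.
#' @param amount absolute dose in mg.
#' @param cap maximum absolute dose in mg applied to the weight-based
#'   rule (default 2000).
#' @param duration infusion duration in minutes (> 0; default 1).
#' @param dose_times start times of the doses in minutes, nondecreasing
#'   (default a single dose at 0).
#' @param label optional regimen label used in reports; defaults to e.g.
#'   `"25 mg/kg"` or `"2000 mg"`.
#' @return An object of class `txa_regimen`.
#' @examples
#' dose_regimen(dose_per_kg = 25)
#' dose_regimen(amount = 2000, duration = 1)
#' @export
dose_regimen <- function(dose_per_kg = NULL, amount = NULL, cap = 2000,
                         duration = 1, dose_times = 0, label = NULL) {
  if (is.null(dose_per_kg) == is.null(amount))
    stop("specify exactly one of 'dose_per_kg' or 'amount'", call. = FALSE)
  if (!is.null(dose_per_kg) && (!is.finite(dose_per_kg) || dose_per_kg <= 0))
    stop("'dose_per_kg' must be positive", call. = FALSE)
  if (!is.null(amount) && (!is.finite(amount) || amount <= 0))
    stop("'amount' must be positive", call. = FALSE)
  if (!is.finite(cap) || cap <= 0) stop("'cap' must be positive", call. = FALSE)
  if (!is.finite(duration) || duration <= 0)
    stop("'duration' must be positive (minutes)", call. = FALSE)
  if (length(dose_times) < 1L || any(!is.finite(dose_times)) ||
      any(dose_times < 0) || is.unsorted(dose_times))
    stop("'dose_times' must be nonnegative and nondecreasing", call. = FALSE)
  if (is.null(label)) {
    label <- if (!is.null(dose_per_kg)) sprintf("%g mg/kg", dose_per_kg)
             else sprintf("%g mg", amount)
  }
  structure(list(dose_per_kg = dose_per_kg, amount = amount, cap = cap,
                 duration = duration, dose_times = dose_times, label = label),
            class = "txa_regimen")
}

#' @export
print.txa_regimen <- function(x, ...) {
  rule <- if (!is.null(x$dose_per_kg))
    sprintf("%g mg/kg (max %g mg/dose)", x$dose_per_kg, x$cap)
  else sprintf("%g mg absolute", x$amount)
  cat(sprintf("TXA regimen [%s]: %s, %g-min infusion, dose(s) at t = %s min\n",
              x$label, rule, x$duration,
              paste(x$dose_times, collapse = ", ")))
  invisible(x)
}

#' Resolve the administered dose for each subject
#'
#' Weight-based regimens give `min(dose_per_kg * weight, cap)` mg;
#' absolute regimens give the fixed amount regardless of weight.
#'
#' @param regimen a [dose_regimen()].
#' @param subjects a subject table.
#' @return Numeric vector of administered doses (mg) per subject.
#' @examples
#' s <- txa_subjects(weight = c(58.2, 100), plt = 300, nirs = 65, il8 = 20)
#' resolve_dose(dose_regimen(dose_per_kg = 25), s)  # 1455, 2000 (capped)
#' @export
resolve_dose <- function(regimen, subjects) {
  stopifnot(inherits(regimen, "txa_regimen"))
  if (!is.null(regimen$dose_per_kg))
    pmin(regimen$dose_per_kg * subjects$weight, regimen$cap)
  else
    rep(regimen$amount, nrow(subjects))
}

#' Default concentration sampling grid
#'
#' Dense early sampling to capture the end-of-infusion peak, then
#' progressively sparser points out to the 8-h horizon: 0-5 min every
#' minute, 10, 15, 20, 30, 45, 60 min, then every 30 min to 480 min.
#'
#' @param horizon grid end in minutes (default 480 = 8 h).
#' @return Strictly increasing numeric vector of times (min) starting at 0.
#' @export
default_grid <- function(horizon = 480) {
  stopifnot(horizon >= 60)
  c(0, 1, 2, 3, 4, 5, 10, 15, 20, 30, 45, 60,
    seq(90, horizon, by = 30))
}

validate_grid <- function(times) {
  if (length(times) < 2L || any(!is.finite(times)) || any(times < 0) ||
      any(diff(times) <= 0) || times[1] != 0)
    stop("sampling grid must be strictly increasing, nonnegative, and start at 0",
         call. = FALSE)
  invisible(times)
}
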