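#' Typical (covariate-predicted) TXA clearance
#'
#' Evaluates the clearance equation of the adult model at a subject's
#' covariates with zero random effects:
#' \deqn{CL = CL_{typ} \times (WT/70)^{0.75} \times (PLT/196)^{0.468}
#'   \times (NIRS/88)^{-0.29} \times IL8^{-0.0873}}
#' Clearance increases with weight and platelet count and decreases with
#' NIRS saturation and IL-8.  IL-8 enters unnormalized, as in the
#' published final model.
#'
#' @param subjects a subject table ([txa_subjects()]).
#' @param params a [txa_pk_params()] parameter set.
#' @return Numeric vector of clearances (mL/min), one per subject.
#' @examples
#' s <- txa_subjects(weight = 70, plt = 196, nirs = 88, il8 = 1)
#' typical_clearance(s, txa_pk_params())  # 190 at reference covariates
#' @export
typical_clearance <- function(subjects, params = txa_pk_params()) {
  validate_subjects(subjects)
  validate_pk_params(params)
  params$cl_typ *
    (subjects$weight / params$ref_wt)^params$exp_cl_wt *
    (subjects$plt / params$ref_plt)^params$exp_plt *
    (subjects$nirs / params$ref_nirs)^params$exp_nirs *
    subjects$il8^params$exp_il8
}

#' Individual disposition parameters
#'
#' Realizes each subject's two-compartment parameters: covariate-scaled
#' typical values multiplied by the subject's lognormal random effects
#' `exp(eta)`.  Clearance and intercompartmental clearance scale with
#' `(weight/70)^0.75`; both volumes scale linearly with weight.  The
#' clearance covariates (platelets, NIRS, IL-8) act on CL only.
#'
#' @inheritParams typical_clearance
#' @return A `data.frame` with columns `id`, `cl` (mL/min), `v1` (mL),
#'   `q` (mL/min), `v2` (mL).
#' @examples
#' s <- txa_subjects(weight = 70, plt = 196, nirs = 88, il8 = 1)
#' individual_parameters(s)  # typical values: 190, 17300, 80.1, 11400
#' @export
individual_parameters <- function(subjects, params = txa_pk_params()) {
  validate_subjects(subjects)
  validate_pk_params(params)
  wt_frac <- subjects$weight / params$ref_wt
  out <- data.frame(
    id = subjects$id,
    cl = typical_clearance(subjects, params) * exp(subjects$eta_cl),
    v1 = params$v1_typ * wt_frac^params$exp_v1_wt * exp(subjects$eta_v1),
    q  = params$q_typ  * wt_frac^params$exp_q_wt  * exp(subjects$eta_q),
    v2 = params$v2_typ * wt_frac^params$exp_v2_wt * exp(subjects$eta_v2),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(out[-1]))) || any(as.matrix(out[-1]) <= 0))
    stop("individual parameters must be strictly positive and finite",
         call. = FALSE)
  out
}

#' Hybrid and micro rate constants of the two-compartment model
#'
#' Converts individual parameters (CL, V1, Q, V2) into micro constants
#' `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2` and the hybrid (macro)
#' rate constants `alpha > beta`, the roots of
#' \eqn{s^2 - (k10+k12+k21)s + k10\,k21 = 0}, together with the unit-bolus
#' biexponential coefficients `coef_a = (alpha-k21)/(alpha-beta)` and
#' `coef_b = (k21-beta)/(alpha-beta)` (`coef_a + coef_b = 1`).
#'
#' For strictly positive parameters the discriminant is positive unless
#' `k12 = 0` with `k10 = k21`, where the two phases coalesce; that
#' degenerate boundary is resolved by separating the roots by a relative
#' epsilon (1e-9), which changes concentrations by a negligible amount and
#' keeps the downstream biexponential formulas defined.
#'
#' @param ind one row of [individual_parameters()] output (or any list
#'   with elements `cl`, `v1`, `q`, `v2`).
#' @return A list of class `txa_disposition` with elements `alpha`,
#'   `beta`, `coef_a`, `coef_b`, `k10`, `k12`, `k21`, `v1`, `cl`,
#'   and `degenerate` (logical flag).
#' @export
disposition_constants <- function(ind) {
  cl <- ind$cl; v1 <- ind$v1; q <- ind$q; v2 <- ind$v2
  stopifnot(is.finite(cl), is.finite(v1), is.finite(q), is.finite(v2),
            cl > 0, v1 > 0, q > 0, v2 > 0)
  k10 <- cl / v1
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- s^2 - 4 * k10 * k21
  degenerate <- disc <= (s^2 * 1e-14)
  if (degenerate) {
    # coalescing phases: split the double root by a relative epsilon
    root <- s / 2
    eps <- root * 1e-9
    alpha <- root + eps
    beta <- root - eps
  } else {
    sq <- sqrt(disc)
    alpha <- (s + sq) / 2
    beta <- (s - sq) / 2
  }
  structure(list(
    alpha = alpha, beta = beta,
    coef_a = (alpha - k21) / (alpha - beta),
    coef_b = (k21 - beta) / (alpha - beta),
    k10 = k10, k12 = k12, k21 = k21,
    v1 = v1, cl = cl, degenerate = degenerate
  ), class = "txa_disposition")
}
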