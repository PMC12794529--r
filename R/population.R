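#' Default pediatric covariate sampling ranges
#'
#' Published summary ranges for pediatric trauma patients: the lower and
#' upper bounds are either the 25th and 75th percentiles (median [IQR]
#' sources) or mean +/- one standard deviation (mean [SD] sources).
#' Endpoints are inclusive; they summarize cohorts, they are not hard
#' physiologic limits.
#'
#' @return A named list with elements `age` (years), `weight` (kg),
#'   `plt` (K/uL), `nirs` (%), `il8` (pg/mL); each a `c(lower, upper)`
#'   pair.
#' @export
pediatric_covariate_ranges <- function() {
  list(
    age = c(4.7, 15.4),
    weight = c(17.7, 58.2),
    plt = c(205, 433),
    nirs = c(51, 80),
    il8 = c(6.6, 50.2)
  )
}

#' Default adult covariates
#'
#' Median covariate values at admission in the adult trauma trial
#' population underlying the model.
#'
#' @return A named list with elements `weight` (kg), `plt` (K/uL),
#'   `nirs` (%), `il8` (pg/mL), `age` (`NA`, not modeled).
#' @export
adult_reference_covariates <- function() {
  list(weight = 80.1, plt = 197, nirs = 88, il8 = 20.3, age = NA_real_)
}

validate_ranges <- function(ranges) {
  req <- c("age", "weight", "plt", "nirs", "il8")
  miss <- setdiff(req, names(ranges))
  if (length(miss))
    stop("covariate ranges missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (f in req) {
    r <- ranges[[f]]
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)))
      stop("range for '", f, "' must be two finite numbers", call. = FALSE)
    if (r[1] > r[2])
      stop("range for '", f, "' has lower > upper", call. = FALSE)
    if (r[1] <= 0)
      stop("range for '", f, "' must be strictly positive", call. = FALSE)
  }
  invisible(ranges)
}

#' Sample lognormal random effects
#'
#' Draws independent normal random effects `eta ~ N(0, omega^2)` for each
#' of the four disposition parameters, one quadruple per subject.
#' Seeded draws are reproducible.
#'
#' @param params a [txa_pk_params()] set supplying the four variances.
#' @param n number of subjects.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return A `data.frame` with columns `eta_cl`, `eta_v1`, `eta_q`,
#'   `eta_v2` and `n` rows.
#' @export
sample_random_effects <- function(params, n, seed = NULL) {
  validate_pk_params(params)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    eta_cl = stats::rnorm(n, 0, sqrt(params$omega2_cl)),
    eta_v1 = stats::rnorm(n, 0, sqrt(params$omega2_v1)),
    eta_q  = stats::rnorm(n, 0, sqrt(params$omega2_q)),
    eta_v2 = stats::rnorm(n, 0, sqrt(params$omega2_v2))
  )
}

#' Generate the virtual adult cohort
#'
#' All subjects share the fixed adult median covariates; between-subject
#' differences come only from independently sampled random effects on the
#' disposition parameters.
#'
#' @param n number of subjects (default 1000).
#' @param covariates named list of fixed covariate values
#'   (`weight`, `plt`, `nirs`, `il8`, optionally `age`); defaults to
#'   [adult_reference_covariates()].
#' @param params a [txa_pk_params()] set.
#' @param seed integer seed for the random-effect draws.
#' @return A subject table ([txa_subjects()]).
#' @examples
#' a <- generate_adult_cohort(n = 5, seed = 1)
#' unique(a$weight)  # 80.1
#' @export
generate_adult_cohort <- function(n = 1000,
                                  covariates = adult_reference_covariates(),
                                  params = txa_pk_params(),
                                  seed = NULL) {
  stopifnot(n >= 1)
  req <- c("weight", "plt", "nirs", "il8")
  miss <- setdiff(req, names(covariates))
  if (length(miss))
    stop("fixed adult covariates missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  eta <- sample_random_effects(params, n, seed)
  age <- if (!is.null(covariates$age)) covariates$age else NA_real_
  txa_subjects(
    id = sprintf("adult_%04d", seq_len(n)),
    weight = rep(covariates$weight, n), plt = rep(covariates$plt, n),
    nirs = rep(covariates$nirs, n), il8 = rep(covariates$il8, n),
    age = rep(age, n),
    eta_cl = eta$eta_cl, eta_v1 = eta$eta_v1,
    eta_q = eta$eta_q, eta_v2 = eta$eta_v2
  )
}

#' Generate the virtual pediatric trauma population
#'
#' Each covariate (age, weight, platelet count, NIRS, IL-8) is drawn
#' independently and uniformly within its closed published range; random
#' effects are drawn as in [sample_random_effects()].  No joint
#' covariate distribution (e.g. weight-age pairing) is imposed -- none is
#' published.  Age is carried for reporting only.
#'
#' @param n number of subjects (default 1000).
#' @param ranges covariate ranges, as [pediatric_covariate_ranges()].
#' @param params a [txa_pk_params()] set.
#' @param seed integer seed; covariates and etas both flow from it.
#' @return A subject table ([txa_subjects()]).
#' @examples
#' p <- generate_pediatric_population(n = 20, seed = 42)
#' range(p$weight)  # within 17.7-58.2
#' @export
generate_pediatric_population <- function(n = 1000,
                                          ranges = pediatric_covariate_ranges(),
                                          params = txa_pk_params(),
                                          seed = NULL) {
  stopifnot(n >= 1)
  validate_ranges(ranges)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(r) stats::runif(n, r[1], r[2])
  cov <- lapply(ranges[c("weight", "plt", "nirs", "il8", "age")], draw)
  eta <- sample_random_effects(params, n, seed = NULL)
  txa_subjects(
    id = sprintf("ped_%04d", seq_len(n)),
    weight = cov$weight, plt = cov$plt, nirs = cov$nirs, il8 = cov$il8,
    age = cov$age,
    eta_cl = eta$eta_cl, eta_v1 = eta$eta_v1,
    eta_q = eta$eta_q, eta_v2 = eta$eta_v2
  )
}
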