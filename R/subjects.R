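#' Build a table of virtual subjects
#'
#' A subject table is a plain `data.frame` with one row per virtual patient:
#' an identifier, the four model covariates (weight, platelet count, NIRS
#' saturation, IL-8), age (carried for reporting only -- the model has no
#' age term), and the realized lognormal random effects on the four
#' disposition parameters.
#'
#' @param id subject identifiers (coerced to character).
#' @param weight body weight (kg), strictly positive.
#' @param plt platelet count (K/uL), strictly positive.
#' @param nirs NIRS skeletal-muscle oxygen saturation (%), strictly positive.
#' @param il8 interleukin-8 plasma concentration (pg/mL), strictly positive.
#' @param age age in years; may be `NA` (reporting only).
#' @param eta_cl,eta_v1,eta_q,eta_v2 realized random effects (log scale),
#'   finite; default 0.
#' @return A `data.frame` with class `txa_subjects` prepended.
#' @examples
#' txa_subjects(weight = 70, plt = 196, nirs = 88, il8 = 1)
#' @export
txa_subjects <- function(id = NULL, weight, plt, nirs, il8, age = NA_real_,
                         eta_cl = 0, eta_v1 = 0, eta_q = 0, eta_v2 = 0) {
  n <- max(length(weight), length(plt), length(nirs), length(il8))
  if (is.null(id)) id <- as.character(seq_len(n))
  df <- data.frame(
    id = as.character(id),
    weight = as.numeric(weight), plt = as.numeric(plt),
    nirs = as.numeric(nirs), il8 = as.numeric(il8),
    age = as.numeric(age),
    eta_cl = as.numeric(eta_cl), eta_v1 = as.numeric(eta_v1),
    eta_q = as.numeric(eta_q), eta_v2 = as.numeric(eta_v2),
    stringsAsFactors = FALSE
  )
  class(df) <- c("txa_subjects", "data.frame")
  validate_subjects(df)
  df
}

validate_subjects <- function(s) {
  req <- c("id", "weight", "plt", "nirs", "il8", "age",
           "eta_cl", "eta_v1", "eta_q", "eta_v2")
  miss <- setdiff(req, names(s))
  if (length(miss))
    stop("subject table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(s) < 1L) stop("subject table must have at least one row",
                         call. = FALSE)
  for (f in c("weight", "plt", "nirs", "il8")) {
    v <- s[[f]]
    if (any(!is.finite(v)) || any(v <= 0))
      stop("covariate '", f, "' must be strictly positive and finite",
           call. = FALSE)
  }
  for (f in c("eta_cl", "eta_v1", "eta_q", "eta_v2")) {
    if (any(!is.finite(s[[f]])))
      stop("random effect '", f, "' must be finite", call. = FALSE)
  }
  invisible(s)
}

#' Export or import a subject table as delimited text
#'
#' Round-trips the full subject table (covariates and realized etas) as
#' tab-separated text so externally constructed cohorts can be injected
#' into the pipeline.
#'
#' @param subjects a subject table (see [txa_subjects()]).
#' @param path file path.
#' @return `read_subjects()` returns a validated subject table;
#'   `write_subjects()` returns `path` invisibly.
#' @export
write_subjects <- function(subjects, path) {
  validate_subjects(subjects)
  utils::write.table(as.data.frame(subjects), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(id = "character"),
                          stringsAsFactors = FALSE)
  class(df) <- c("txa_subjects", "data.frame")
  validate_subjects(df)
  df
}
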