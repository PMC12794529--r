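#' Summarize exposure metrics across a cohort
#'
#' Median and quartiles of each NCA metric over subjects.  Quantiles use
#' the linear-interpolation convention between order statistics
#' (`stats::quantile` type 7); at cohort sizes of 1000 the choice of
#' convention moves the summaries by far less than the Monte Carlo
#' spread.
#'
#' @param metrics a metrics `data.frame` from [nca_batch()].
#' @param label regimen label attached to the summary.
#' @return An object of class `txa_exposure_summary`: a `data.frame`
#'   with one row per metric (`cmax`, the AUC windows, `t_above`) and
#'   columns `median`, `q1`, `q3`; attributes `label` and `n`.
#' @examples
#' m <- data.frame(id = as.character(1:5), dose_mg = 1000,
#'                 cmax = 1:5, tmax = 1, auc_0_4h = 1:5,
#'                 auc_0_8h = 2:6, t_above = 1:5, threshold = 10)
#' summarize_exposure(m)["cmax", ]  # median 3, Q1 2, Q3 4
#' @export
summarize_exposure <- function(metrics, label = "") {
  if (is.null(metrics) || nrow(metrics) == 0L)
    stop("no metrics to summarize", call. = FALSE)
  metric_cols <- setdiff(names(metrics),
                         c("id", "dose_mg", "tmax", "threshold"))
  qs <- t(vapply(metric_cols, function(cn)
    stats::quantile(metrics[[cn]], c(0.5, 0.25, 0.75), names = FALSE,
                    type = 7),
    numeric(3)))
  out <- data.frame(median = qs[, 1], q1 = qs[, 2], q3 = qs[, 3],
                    row.names = metric_cols)
  attr(out, "label") <- label
  attr(out, "n") <- nrow(metrics)
  class(out) <- c("txa_exposure_summary", "data.frame")
  out
}

#' @export
print.txa_exposure_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Exposure summary [%s], n = %d; median (Q1-Q3)\n",
              attr(x, "label"), attr(x, "n")))
  for (m in rownames(x))
    cat(sprintf("  %-9s %s (%s-%s)\n", m,
                signif(x[m, "median"], digits),
                signif(x[m, "q1"], digits), signif(x[m, "q3"], digits)))
  invisible(x)
}

summary_median <- function(s, metric) s[metric, "median"]

#' Select the candidate dose whose median Cmax best matches the reference
#'
#' "Most similar" is operationalized as the minimum absolute deviation of
#' the median-Cmax ratio (candidate/reference) from 1; a scale-free
#' criterion.  Ties break toward the lower dose.
#'
#' @param candidates numeric vector of candidate doses (mg/kg).
#' @param summaries list of `txa_exposure_summary`, parallel to
#'   `candidates`.
#' @param adult_ref the reference `txa_exposure_summary`.
#' @return A list: `dose` (selected candidate), `ratios` (named vector of
#'   median-Cmax ratios).
#' @export
select_dose_by_cmax <- function(candidates, summaries, adult_ref) {
  stopifnot(length(candidates) >= 1L,
            length(candidates) == length(summaries))
  ref <- summary_median(adult_ref, "cmax")
  ratios <- vapply(summaries, summary_median, numeric(1), metric = "cmax") / ref
  names(ratios) <- as.character(candidates)
  dev <- abs(ratios - 1)
  ord <- order(dev, candidates)  # ties -> lower dose
  list(dose = candidates[ord[1]], ratios = ratios)
}

#' Select the candidate dose whose median AUC best matches the reference
#'
#' Nearest median-AUC ratio to 1 for the chosen window, with a shortfall
#' flag raised when every candidate's median AUC falls below the
#' reference median (i.e. no candidate reaches the reference exposure).
#' Also reports, per candidate, whether its interquartile range overlaps
#' the reference IQR.
#'
#' @inheritParams select_dose_by_cmax
#' @param which AUC window: `"auc_0_8h"` (default) or `"auc_0_4h"`.
#' @return A list: `dose`, `shortfall` (logical), `ratios`,
#'   `iqr_overlap` (named logical vector).
#' @export
select_dose_by_auc <- function(candidates, summaries, adult_ref,
                               which = c("auc_0_8h", "auc_0_4h")) {
  which <- match.arg(which)
  stopifnot(length(candidates) >= 1L,
            length(candidates) == length(summaries))
  ref <- summary_median(adult_ref, which)
  med <- vapply(summaries, summary_median, numeric(1), metric = which)
  ratios <- med / ref
  names(ratios) <- as.character(candidates)
  dev <- abs(ratios - 1)
  ord <- order(dev, candidates)
  overlap <- vapply(summaries, function(s)
    s[which, "q3"] >= adult_ref[which, "q1"] &&
    s[which, "q1"] <= adult_ref[which, "q3"], logical(1))
  names(overlap) <- as.character(candidates)
  list(dose = candidates[ord[1]], shortfall = all(med < ref),
       ratios = ratios, iqr_overlap = overlap)
}

#' Assemble the adult-versus-pediatric dose-comparison report
#'
#' Combines the adult reference summary with per-dose pediatric
#' summaries: median ratios for every metric, the Cmax-matched dose, the
#' AUC-matched dose for both windows with shortfall flags, and IQR
#' overlap indicators.
#'
#' @param adult_ref reference `txa_exposure_summary`.
#' @param candidates numeric vector of pediatric candidate doses (mg/kg).
#' @param summaries list of pediatric `txa_exposure_summary`, parallel to
#'   `candidates`.
#' @return An object of class `txa_comparison`.
#' @export
compare_doses <- function(adult_ref, candidates, summaries) {
  stopifnot(length(candidates) == length(summaries),
            length(candidates) >= 1L)
  metrics <- rownames(adult_ref)
  ratio_tab <- sapply(metrics, function(m) {
    ref <- summary_median(adult_ref, m)
    vapply(summaries, summary_median, numeric(1), metric = m) / ref
  })
  ratio_tab <- matrix(ratio_tab, nrow = length(candidates),
                      dimnames = list(as.character(candidates), metrics))
  by_cmax <- select_dose_by_cmax(candidates, summaries, adult_ref)
  by_auc4 <- select_dose_by_auc(candidates, summaries, adult_ref, "auc_0_4h")
  by_auc8 <- select_dose_by_auc(candidates, summaries, adult_ref, "auc_0_8h")
  structure(list(
    adult = adult_ref,
    candidates = candidates,
    pediatric = stats::setNames(summaries, as.character(candidates)),
    ratios = ratio_tab,
    selected_by_cmax = by_cmax$dose,
    selected_by_auc_0_4h = by_auc4$dose,
    selected_by_auc_0_8h = by_auc8$dose,
    auc_shortfall = c(auc_0_4h = by_auc4$shortfall,
                      auc_0_8h = by_auc8$shortfall),
    iqr_overlap = rbind(auc_0_4h = by_auc4$iqr_overlap,
                        auc_0_8h = by_auc8$iqr_overlap)
  ), class = "txa_comparison")
}

#' @export
print.txa_comparison <- function(x, digits = 4, ...) {
  fmt <- function(s, m)
    sprintf("%s (%s-%s)", signif(s[m, "median"], digits),
            signif(s[m, "q1"], digits), signif(s[m, "q3"], digits))
  metrics <- rownames(x$adult)
  labs <- c(sprintf("Adult [%s]", attr(x$adult, "label")),
            sprintf("Ped %s mg/kg", names(x$pediatric)))
  cols <- cbind(vapply(metrics, fmt, character(1), s = x$adult),
                sapply(x$pediatric, function(s)
                  vapply(metrics, fmt, character(1), s = s)))
  colnames(cols) <- labs
  cat("Model-predicted TXA exposure, median (Q1-Q3)\n\n")
  print(cols, quote = FALSE)
  cat(sprintf("\nDose matching the adult median Cmax:    %g mg/kg\n",
              x$selected_by_cmax))
  cat(sprintf("Dose nearest the adult median AUC 0-4h: %g mg/kg%s\n",
              x$selected_by_auc_0_4h,
              if (x$auc_shortfall["auc_0_4h"]) " (all candidates fall short)" else ""))
  cat(sprintf("Dose nearest the adult median AUC 0-8h: %g mg/kg%s\n",
              x$selected_by_auc_0_8h,
              if (x$auc_shortfall["auc_0_8h"]) " (all candidates fall short)" else ""))
  invisible(x)
}

#' Write a dose-comparison report as delimited text
#'
#' One row per regimen per metric with median and quartiles, mirroring
#' the printed comparison table.
#'
#' @param report a `txa_comparison`.
#' @param path file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path) {
  rows <- list()
  add <- function(label, s) {
    data.frame(regimen = label, metric = rownames(s),
               median = s$median, q1 = s$q1, q3 = s$q3,
               n = attr(s, "n"), stringsAsFactors = FALSE)
  }
  rows[[1]] <- add(paste0("adult_", attr(report$adult, "label")),
                   report$adult)
  for (d in names(report$pediatric))
    rows[[length(rows) + 1L]] <- add(paste0("pediatric_", d, "_mg_kg"),
                                     report$pediatric[[d]])
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sweep infusion duration at a fixed weight-based dose
#'
#' Re-simulates the same cohort (same subjects, same realized random
#' effects) at several administration durations and summarizes exposure
#' for each.  AUC metrics are expected to be nearly invariant to
#' duration over 1-10 min, while the true peak concentration can only
#' decrease as the infusion lengthens.
#'
#' @param subjects pediatric subject table.
#' @param params a [txa_pk_params()] set.
#' @param dose_per_kg weight-based dose (mg/kg) with the standard 2 g cap.
#' @param durations vector of infusion durations (min).
#' @param grid sampling grid (min).
#' @param threshold time-above threshold (mg/L).
#' @param error_mode `"proportional"` or `"none"`.
#' @param seed integer seed; each duration gets an independent
#'   residual-error stream derived from it.
#' @return A named list of `txa_exposure_summary` (one per duration),
#'   class `txa_duration_sweep`.
#' @export
infusion_duration_sweep <- function(subjects, params = txa_pk_params(),
                                    dose_per_kg = 25,
                                    durations = c(1, 5, 10),
                                    grid = default_grid(),
                                    threshold = 10,
                                    error_mode = c("proportional", "none"),
                                    seed = NULL) {
  error_mode <- match.arg(error_mode)
  stopifnot(all(durations > 0))
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(durations))
  out <- lapply(seq_along(durations), function(i) {
    reg <- dose_regimen(dose_per_kg = dose_per_kg, duration = durations[i],
                        label = sprintf("%g mg/kg over %g min",
                                        dose_per_kg, durations[i]))
    prof <- simulate_cohort(subjects, params, reg, grid, error_mode,
                            seed = if (is.null(seed)) NULL else sub_seeds[i])
    summarize_exposure(nca_batch(prof, threshold = threshold),
                       label = reg$label)
  })
  names(out) <- sprintf("%g_min", durations)
  structure(out, class = "txa_duration_sweep", durations = durations)
}

#' @export
print.txa_duration_sweep <- function(x, ...) {
  cat("Infusion-duration sweep\n")
  for (s in x) { print(s); cat("\n") }
  invisible(x)
}

#' Plot median concentration-time profiles per regimen
#'
#' Base-graphics analog of the usual simulated time-concentration
#' figure: the median true concentration across the cohort at each grid
#' time, one line per regimen, with the 10 mg/L threshold marked.
#'
#' @param profile_sets named list of `txa_profiles` (one element per
#'   regimen).
#' @param threshold reference concentration drawn as a horizontal line
#'   (mg/L); `NULL` to omit.
#' @param log_y logical; log-scale concentration axis.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the matrix of median concentrations
#'   (time x regimen).
#' @export
plot_profiles <- function(profile_sets, threshold = 10, log_y = TRUE, ...) {
  stopifnot(length(profile_sets) >= 1L)
  times <- profile_sets[[1]][[1]]$times
  med <- sapply(profile_sets, function(ps) {
    cc <- sapply(ps, function(p) p$c_true)
    apply(cc, 1, stats::median)
  })
  keep <- times > 0
  graphics::matplot(times[keep] / 60, med[keep, , drop = FALSE], type = "l",
                    lty = 1, lwd = 2, col = seq_len(ncol(med)),
                    log = if (log_y) "y" else "",
                    xlab = "Time (h)", ylab = "TXA concentration (mg/L)", ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 3)
  graphics::legend("topright", legend = colnames(med), lty = 1, lwd = 2,
                   col = seq_len(ncol(med)), bty = "n")
  invisible(med)
}
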