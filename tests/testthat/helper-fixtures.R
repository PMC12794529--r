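# Shared fixtures: reference subjects and random positive parameter sets.

reference_subject <- function() {
  txa_subjects(weight = 70, plt = 196, nirs = 88, il8 = 1)
}

adult_median_subject <- function() {
  txa_subjects(weight = 80.1, plt = 197, nirs = 88, il8 = 20.3)
}

# individual two-compartment parameter sets spanning a broad positive range
random_parameter_sets <- function(n, seed = 100) {
  set.seed(seed)
  data.frame(
    id = as.character(seq_len(n)),
    cl = exp(runif(n, log(10), log(1000))),
    v1 = exp(runif(n, log(1000), log(50000))),
    q  = exp(runif(n, log(5), log(500))),
    v2 = exp(runif(n, log(1000), log(50000)))
  )
}

# numerical reference: integrate the two-compartment amounts with lsoda,
# piecewise over the infusion window, and report central concentration (mg/L)
ode_oracle <- function(ind, dose, dur, times) {
  k10 <- ind$cl / ind$v1; k12 <- ind$q / ind$v1; k21 <- ind$q / ind$v2
  deriv <- function(t, y, parms) {
    list(c(parms$rate - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  t1 <- sort(unique(c(0, times[times <= dur], dur)))
  out1 <- deSolve::lsoda(c(0, 0), t1, deriv, list(rate = dose / dur),
                         rtol = 1e-10, atol = 1e-10)
  y_end <- out1[nrow(out1), 2:3]
  t2 <- sort(unique(c(dur, times[times > dur])))
  out2 <- if (length(t2) > 1)
    deSolve::lsoda(y_end, t2, deriv, list(rate = 0),
                   rtol = 1e-10, atol = 1e-10)
  else NULL
  lookup <- rbind(out1, out2)
  conc <- approx(lookup[, 1], lookup[, 2], xout = times, ties = "ordered")$y
  1000 * conc / ind$v1
}
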