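---
title: "Extrapolating tranexamic acid exposure from adult to pediatric trauma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extrapolating tranexamic acid exposure from adult to pediatric trauma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txasim)
```

## The problem

There are no pharmacokinetic data for tranexamic acid (TXA) in children with
severe trauma-related bleeding, so pediatric dosing must be extrapolated.
`txasim` implements the standard model-informed route: take a population
pharmacokinetic (popPK) model estimated in adult trauma patients, scale it to
children with allometric weight relationships, simulate a virtual pediatric
population, and pick the weight-based bolus whose exposure best matches the
adult standard of care (2 g IV bolus).

Two exposure targets pull in different directions. The peak concentration
(Cmax) carries the known dose-toxicity relationship (seizures at high peaks),
while total exposure (AUC) and the time above 10 mg/L — the in-vitro
concentration giving roughly 80% inhibition of fibrinolysis — track
antifibrinolytic effect. The comparison report therefore selects one dose by
Cmax matching and reports the AUC-nearest dose, with a shortfall flag when no
candidate reaches the adult total exposure.

## Model and assumptions

Disposition is a linear two-compartment model with elimination from the
central compartment. Typical values at a subject's covariates are

$$CL = 190\,(WT/70)^{0.75}(PLT/196)^{0.468}(NIRS/88)^{-0.29}IL8^{-0.0873}
\quad \text{mL/min}$$
$$V_1 = 17300\,(WT/70), \qquad Q = 80.1\,(WT/70)^{0.75}, \qquad
V_2 = 11400\,(WT/70)$$

and each parameter is multiplied by a subject-specific lognormal random
effect $e^{\eta}$, $\eta \sim N(0, \omega^2)$, with
$\omega^2 = 0.106, 0.0688, 0.879, 0.0589$ for CL, V1, Q, V2. Observed
concentrations carry proportional residual error,
$C_{obs} = C_{true}(1+\varepsilon)$, $\varepsilon \sim N(0, 0.0238)$,
truncated below at zero.

Assumptions worth making explicit:

* **Two published parameterizations.** The adult model is reported both as
  final equations (CL typical 190 mL/min, IL-8 exponent $-0.0873$) and as a
  parameter-estimate table (192, $-0.0887$); the two disagree by about 1% in
  clearance. The equations are stated to be the model used for simulation,
  so they are the default; `txa_pk_params(variant = "estimate_table")`
  selects the tabulated pair. Which pair produced the published tables is
  not recoverable from either, and the difference is far inside the Monte
  Carlo spread at $n = 1000$.
* **IL-8 enters unnormalized** (no division by a reference), exactly as the
  final model prints it, unlike the platelet and NIRS terms.
* **Random effects are independent** (diagonal $\omega$ matrix) — no
  covariances are reported — and the printed $e^{0.106}$-style factors are
  read as placeholders for $e^{\eta}$ with the tabulated variances, not as
  fixed multipliers; fixed multipliers would inflate every typical value
  and contradict their labeling as inter-individual variability.
* **Covariates are constants.** The model applies admission/summary values
  for the whole 8-h window; no time-courses are modeled.
* **The model has no age term.** Age is sampled and carried for reporting
  only. Children younger than ~1 year would need glomerular-filtration
  maturation modeling, which is out of scope; the pediatric age range
  starts at 4.7 years, where GFR is adult-like.

## Simulation machinery

Concentrations come from the closed-form solution of the two-compartment
system for zero-order infusion: micro constants $k_{10} = CL/V_1$,
$k_{12} = Q/V_1$, $k_{21} = Q/V_2$; hybrid rate constants $\alpha > \beta$
as roots of $s^2 - (k_{10}+k_{12}+k_{21})s + k_{10}k_{21}$; rising
biexponential during the infusion and biexponential decay after, superposed
over dose times. The solution is linear in dose, continuous at the infusion
end, and its total area is exactly $dose/CL$ — properties the test suite
checks pointwise and against an adaptive ODE integration (`deSolve::lsoda`,
relative tolerance $10^{-6}$).

Numerical conventions:

* **Units**: mg, mL, min internally; concentrations reported in mg/L
  (mg/mL × 1000), AUC in mg·min/L, time-above-threshold in hours.
* **Sampling grid** (none is published): 0-5 min every minute,
  then 10, 15, 20, 30, 45, 60 min, then every 30 min to 480 min. Dense
  early points capture the 1-min peak; the 8-h horizon supports the
  AUC$_{0-8h}$ window.
* **Coalescing phases**: if the discriminant vanishes to relative
  $10^{-14}$ (only reachable as $Q \to 0$ with $k_{10} = k_{21}$), the
  double root is split by a relative epsilon of $10^{-9}$ and flagged;
  downstream formulas stay defined with negligible error.
* **NCA**: linear trapezoid (log-linear would differ by <1% on this grid);
  AUC window ends falling between grid points close the last panel by
  linear interpolation; threshold crossings are located by linear
  interpolation on each bracketing segment and multiple crossings
  accumulate; Cmax takes the grid maximum with the earliest time on ties.
* **Quantiles**: linear interpolation between order statistics
  (`quantile` type 7). The convention is documented because none is stated
  for the published medians; alternatives move the summaries by much less
  than the Monte Carlo spread at $n = 1000$.
* **Seeding**: one root seed is split deterministically into per-stage
  streams (adult population, pediatric population, residual error per
  regimen, duration sweep), so switching the error mode off does not
  perturb the population draws, and runs are bit-reproducible.

**Cmax uses the observed (noisy) series by default.** The published median
adult Cmax (117.1 mg/L) exceeds the noiseless ceiling $dose/V_1 \approx
101$ mg/L — which per-kg dosing makes weight-invariant, since $V_1$ scales
linearly with weight — by ~15%. That excess is what one gets by taking the
maximum of several noise-perturbed near-peak samples with a proportional
SD of $\sqrt{0.0238} \approx 0.154$, so the noisy-max convention is the
default and reproduces the published peaks; a noiseless mode
(`error_mode = "none"`) backs the structural property tests.

## The virtual populations

The generator emulates the study conditions, not real patients:

* **Adults**: all subjects share the fixed median covariates (WT 80.1 kg,
  PLT 197 K/uL, NIRS 88%, IL-8 20.3 pg/mL); variability comes from the
  random effects alone. The allometric factor for 80.1 kg is applied (the
  alternative — simulating a 70-kg reference — is not what the covariate
  table describes).
* **Children**: each covariate is drawn independently and uniformly within
  its closed published range (the ranges are IQRs or mean±SD summaries of
  pediatric trauma cohorts). "Random sampling from ranges" is all the
  source specifies; uniform and independent is the simplest consistent
  reading, and the constructor accepts externally built cohorts (delimited
  text) when richer joint distributions are wanted.

What this does **not** emulate: covariate correlations (weight-age growth
pairing, platelet-injury severity), covariate time-courses during
resuscitation, inter-occasion variability (none reported), or children
outside 4.7-15.4 years. Passing tests therefore demonstrate agreement with
the published simulation experiment, not predictive accuracy in real
children — the extrapolation itself (adult covariate effects applied to
children) is a clinical assumption awaiting validation.

## Dose selection logic

"Most similar" is operationalized as the minimum $|{\rm ratio} - 1|$ of
candidate-to-reference medians — scale-free, with ties broken toward the
lower dose (toxicity-conservative). The AUC selector also raises a
shortfall flag when every candidate median sits below the reference and
reports per-candidate IQR overlap with the reference IQR.

One internal tension in the published analysis is worth recording: its prose
states no pediatric dose reached the adult AUC in either window, but its own
exposure table puts the 35 mg/kg AUC$_{0-4h}$ median (8770 mg·min/L) marginally
*above* the adult median (8738). Fed the printed medians, the package's
arithmetic raises the shortfall flag for the 0-8 h window only, and
simulation runs at $n = 1000$ land the same way (35 mg/kg at ~1.00-1.02×
the adult AUC$_{0-4h}$). The package reports what the numbers say rather
than the prose.

## Problem sizes and runtime

The shipped analysis uses 1000 subjects per cohort (the published cohort
size), five regimens plus a three-duration sweep — a few seconds on one
core. Property tests use what each property needs: $10^5$ draws for
variance recovery, $10^4$ for distribution shape, 100-1000 random
parameter sets for the algebraic identities.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `dose_per_kg` candidates | 20, 25, 30, 35 | mg/kg | candidate bolus sweep |
| `cap` | 2000 | mg | adult maximum per dose |
| `duration` | 1 | min | bolus operationalized as 1-min infusion |
| `sweep_durations` | 1, 5, 10 | min | administration-time sensitivity |
| `threshold` | 10 | mg/L | ~80% fibrinolysis inhibition in vitro |
| `horizon` | 480 | min | supports AUC 0-8 h |
| `error_mode` | proportional | — | matches the published Cmax convention |
| `n` | 1000 | subjects | published cohort size |

All of these flow through one validated configuration
(`validate_config()`, YAML/JSON) and a single root seed.
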