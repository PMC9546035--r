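---
title: "Methods: recombination corrections and calorimetric reference dosimetry at ultrahigh dose rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recombination corrections and calorimetric reference dosimetry at ultrahigh dose rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uhdrdosim)
```

## The physical problem

At FLASH dose rates (tens of Gy/s) the charge collected by an ionization
chamber underestimates the charge produced in its air cavity, because ions
recombine before reaching the electrodes. Reference dosimetry then hinges on
the recombination correction factor $k_s = Q_p/Q_c$ (produced over
collected charge, the reciprocal of the collection efficiency), and on an
independent dose-rate-insensitive reference — here a graphite calorimeter —
against which the corrected chamber dose can be compared.

For a quasi-continuous scanned proton beam (cyclotron micro-pulses orders
of magnitude shorter and denser than the ion transit time) the continuous-beam
theory applies. This package treats the beam as continuous throughout;
pulsed-beam Boag formulas and free-electron corrections are deliberately out
of scope.

## Saturation-curve models

All extrapolation methods work on the inverse collected charge as a
function of bias voltage $V$:

* **Linear (volume recombination only):** $1/Q_c = 1/Q_p + k_c/V^2$.
  Valid when collection efficiency exceeds ~0.7; `ks_at()` flags results
  below that bound. $k_c$ (nC$^{-1}$V$^2$) bundles chamber geometry,
  charge density and ion mobility, and grows with dose rate.
* **Niatel (initial + volume):** $1/Q_c = 1/Q_p + (a/Q_p)/V + k_c/V^2$,
  where the chamber-specific parameter $a$ (V) captures recombination
  within single ionization tracks, dose-rate independent.
* **Charge multiplication:** $1/Q_c = (1/Q_p + (a/Q_p)/V + k_c/V^2)
  e^{-\gamma V}$. Small-gap chambers develop field strengths
  (`electric_field_strength()`; 500 V/mm for a 0.6 mm gap at 300 V) where
  gas gain adds non-dosimetric charge near saturation; the exponential
  factor models that excess, and the *total* correction
  $k_s k_{s,CM} = (1 + a/V + k_cQ_p/V^2)e^{-\gamma V}$ may fall below
  unity.
* **Two-voltage technique:** the protocol estimator
  $k_s = ((V_1/V_2)^2-1)/((V_1/V_2)^2-Q_1/Q_2)$ at ratio 3, needing only
  two readings.

`ks_at()` on a charge-multiplication fit returns the total correction in
`ks` with $e^{-\gamma V}$ exposed separately as `ks_cm`, so the
recombination-only factor is `ks/ks_cm`. This matches how
multiplication-corrected $k_s$ curves are plotted in practice, while
keeping the components recoverable.

## Fitting and uncertainty choices

Several numerical choices are genuinely open and fixed as follows:

* **Weighting.** Fits minimize inverse-variance-weighted residuals of
  $1/Q_c$, with $u(1/Q_c) = u(Q_c)/Q_c^2$ by first-order transformation of
  the per-voltage standard errors. When all SEs are zero (noise-free or
  single readings) the fit falls back to ordinary least squares.
* **Covariance.** With weights from known measurement variances the
  parameter covariance is $(X^TWX)^{-1}$, inflated by the Birge ratio
  $\max(1, \chi^2/\nu)$. The inflation matters: per-voltage SEs estimated
  from 5 repeats are themselves noisy (4 degrees of freedom), and without
  it the claimed $Q_p$ uncertainties are anti-conservative — 3-sigma
  coverage of truth drops to ~92 % in simulation; with it, coverage is
  95–98 %.
* **ks uncertainty** is first-order (delta-method) propagation through the
  full fit covariance; `ks_mc_uncertainty()` provides a seeded Monte-Carlo
  cross-check (default $10^5$ draws), which agrees with the delta method
  to a few percent of the uncertainty itself in the regimes exercised here.
* **Physical constraint $k_c \ge 0$** (charge loss cannot be negative) is
  enforced in the linear and Niatel fits: a negative unconstrained slope
  triggers a warning reporting the unconstrained estimate, then a refit on
  the boundary with the unconstrained slope variance retained.
* **Nonlinear fit protocol.** The charge-multiplication fit is
  Levenberg–Marquardt, started from the Niatel solution with $\gamma = 0$,
  bounded by $Q_p > 0$, $k_c \ge 0$, $0 \le \gamma \le 10^{-2}$ V$^{-1}$
  (gains beyond ~1 %/V would dominate the signal and indicate a broken
  measurement rather than a correction). On non-convergence up to 5
  restarts perturb the start deterministically (fixed sinusoidal jitter, no
  RNG) and probe $\gamma > 0$; the best converged fit wins.
* **Voltage matching** for two-voltage pairs and three-voltage subsets is
  exact after rounding to 0.1 V — electrometer set-points are reported at
  that resolution, and fuzzy matching risks silently pairing wrong points.
  The default three-voltage subset is 50/100/200 V, the customary linear
  region below multiplication onset; it is configurable.
* **Polarity** is metadata: series are analysed per polarity, magnitudes
  are used throughout, and no polarity averaging happens inside the
  recombination module (whether the underlying readings were
  polarity-corrected is generally unknowable downstream).

## Dose determination

`dose_to_water()` applies $D_w = M\,k_{TP}\,k_{pol}\,k_s\,N_{D,w}\,k_Q$.
$k_Q$ is a required user input: beam-quality factors for UHDR proton
beams are not tabulated reliably enough to bake in, and their ~2.1 %
uncertainty class dominates the chamber budget anyway; the dose uncertainty
is the quadrature of the relative uncertainties of $M$, $k_s$ and $k_Q$.
$k_{pol}$ defaults to 1 (apply `k_pol()` explicitly if both polarities were
measured). Reference conditions default to 20 °C / 101.325 kPa and are
configurable for 22 °C calibration labs.

## Calorimetry

The quasi-adiabatic analysis fits a straight line to the pre- and
post-irradiation segments of the core-temperature trace and extrapolates
both to the irradiation-window midpoint; the difference is the
radiation-induced rise $\Delta T$, exact for any linear-drift-plus-step
trace (an identity the tests exercise), with the two extrapolation standard
errors combined in quadrature. Then $D_g = c\,\Delta T$ and
$D_w = D_g\,s_{w,g}\,k_{fl}$ with user-supplied constants — the
stopping-power ratio and fluence correction come from Monte Carlo transport
and are treated as inputs, not computed here. Heat-loss, impurity and
vacuum-gap corrections are absorbed into a single relative type-B
uncertainty (default 1.5 %, standard $k=1$); type A is the SDOM of at
least 20 runs per field (fewer warns), and the combined uncertainty is
their quadrature. This is a deliberately simplified account of a primary
calorimeter's budget, adequate for field-level comparison, not for a
standards laboratory.

## Comparison statistics

Per-field ratios chamber/calorimeter carry, by default, only the chamber
statistical uncertainty — that convention reproduces how comparison tables
are usually printed, with the calorimeter's systematic budget quoted once
globally; a full-quadrature mode is available. Printed ratios are rounded
half-up to 3 decimals. The campaign average is the unweighted mean of
ratios with uncertainty $\max(\text{SDOM}, \overline{u}_{field})$, and
`agreement_score()` reports $z = |r-1|/\sqrt{u_r^2+u_{sys}^2}$ with a
default (configurable, not doctrinal) significance threshold of 1.5; with
the standard ionometric (2.3 %) and calorimetric (1.5 %) budgets even a
3 % ratio excess yields $z \approx 1.2$.

## What the synthetic generator emulates — and what it does not

`simulate_charge_series()` inverts the full charge-multiplication forward
model and adds multiplicative Gaussian noise (default 0.1 % relative SD, 5
repeats per voltage — consistent with sub-0.7 % reproducibility of modern
electrometers); per-voltage means and SEs are reported exactly as a
measurement campaign would. $k_c$ scales linearly with dose rate, the
expected behaviour when volume recombination tracks the charge-production
rate in a continuous beam. Two archetypes set the scale:

* `markus_like` (1 mm gap): $Q_p = 5.03$ nC, $a = 0.2$ V,
  $k_c = 1.6\,\dot D$, $\gamma = 0$ — two-voltage $k_s$(300 V) spans
  ~1.001–1.006 over 5–62 Gy/s.
* `ppc05_like` (0.6 mm gap): $Q_p = 12.6$ nC, $a = 0.4$ V,
  $k_c = 0.30\,\dot D$, $\gamma = 10^{-5}$ V$^{-1}$ — a flat (<0.3 %)
  two-voltage response whose total correction at 300 V sits just below
  unity at low dose rates and crosses above it near 50 Gy/s, and whose
  three-voltage linear extrapolation slightly underestimates $Q_p$.

The generator emulates measurement noise and the recombination/
multiplication physics, but **not**: spot-by-spot PBS delivery structure,
drifts of the beam monitor, polarity asymmetries, leakage currents, or any
LET/depth dependence. Passing closure tests therefore demonstrates that the
estimators are correct for data obeying the stated models at realistic
noise — not that the models exhaust real chamber behaviour.

`simulate_calorimeter_run()` builds drift-plus-step traces (1 Hz sampling,
120 s, 0.5 s irradiation at 60 s by default) whose post-drift line is
anchored so the midpoint-extrapolation identity holds exactly;
`simulate_calorimeter_campaign()` adds 0.04 % relative per-run dose
scatter, the repeatability scale of a well-behaved graphite calorimeter.

## Degenerate inputs and error taxonomy

Classed conditions separate user errors from physics: `uhdr_domain_error`
(non-positive charges, voltages, doses), `uhdr_input_error` (missing
voltages, too few points, unknown methods), `uhdr_degenerate_error`
(inverted saturation curve, $Q_1/Q_2 \ge (V_1/V_2)^2$),
`uhdr_extrapolation_error` (non-positive intercept: no finite saturation
charge), `uhdr_fit_error` (nonlinear non-convergence after restarts).
Campaign drivers skip a series only for a missing two-voltage point (with a
logged warning) or, under `keep_going`, for failed fits.

## Problem sizes

The shipped tests and the acceptance script use campaigns of 7 dose rates ×
5–8 voltages × 5 repeats, 200 replicate seeds for coverage studies, 20-run
calorimeter campaigns, and $5\times10^4$–$10^5$ Monte-Carlo draws — sizes
chosen so the whole suite runs in seconds while leaving the stochastic
assertions with comfortable margins.

## Known limitations

* Continuous-beam formalism only; results do not transfer to pulsed
  electron FLASH beams.
* The charge-multiplication exponential is phenomenological; $\gamma$ has
  no microscopic interpretation and correlates strongly with $a$ and $k_c$
  when the voltage range is narrow — expect inflated joint uncertainties
  below ~8 distinct voltages.
* The calorimeter module is a simplified field-comparison tool; a primary
  standard's full uncertainty budget (heat transfer modelling, impurity
  corrections) is out of scope.
* Which single $k_s$ value should enter a routine dose determination
  (per-field, per-dose-rate, or campaign-level) is a protocol choice left
  to the caller; `recombination_campaign()` provides the full table.
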