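# uhdrdosim

Reference dosimetry analysis for ultrahigh-dose-rate (UHDR / FLASH)
pencil-beam-scanning proton fields, for medical physicists commissioning or
auditing FLASH beamlines. The package answers two coupled questions:

1. **How large is the ion-recombination correction k_s of a plane-parallel
   chamber at FLASH dose rates (5–60 Gy/s), and do the standard protocol
   methods still agree?**
2. **Does the chamber-determined absorbed dose to water agree with a
   dose-rate-independent graphite-calorimeter reference, field by field?**

## The models

An ionization chamber collects a charge Q_c smaller (recombination) or —
for sub-millimetre gaps at high bias — larger (charge multiplication) than
the charge Q_p produced in its cavity. The correction factor is
k_s = Q_p / Q_c, the reciprocal of the collection efficiency. Four
estimators of k_s from a charge-versus-voltage series are implemented:

* **Two-voltage technique** (continuous beam, protocol ratio V1/V2 = 3):

  k_s = ((V1/V2)² − 1) / ((V1/V2)² − Q1/Q2)

* **Linear extrapolation** (Boag volume recombination):
  1/Q_c = 1/Q_p + k_c/V², fitted by weighted least squares; a restriction
  to three low voltages (default 50/100/200 V) gives the *three-voltage
  linear method* used when the high-voltage points are distorted.

* **Niatel quadratic model** (initial + volume recombination):
  1/Q_c = 1/Q_p + (a/Q_p)/V + k_c/V².

* **Semiempirical charge-multiplication model**:
  1/Q_c = (1/Q_p + (a/Q_p)/V + k_c/V²)·exp(−γV), a nonlinear
  Levenberg–Marquardt fit. Its k_s·k_s,CM total correction can dip below
  unity when multiplication gain beats recombination loss.

Dose determination follows the TRS-398 formalism,
D_w = M·k_TP·k_pol·k_s·N_D,w·k_Q, and the calorimeter chain is
ΔT → D_graphite = c·ΔT → D_w = D_g·s_w,g·k_fl, with the radiation-induced
temperature rise ΔT extracted by extrapolating pre- and post-irradiation
linear drifts to the irradiation-window midpoint. Chamber and calorimeter
doses are compared per field as ratios with combined uncertainties and a
z-style agreement score.

All fits propagate charge standard errors through inverse-variance weights,
report parameter covariances (Birge-inflated when the residuals exceed the
claimed measurement variances), and k_s uncertainties by the delta method
with a seeded Monte-Carlo cross-check.

A seeded synthetic-data generator (`default_campaign()`,
`simulate_calorimeter_run()`) emulates complete measurement campaigns from
the forward models, so the whole pipeline is testable without experimental
raw data.

## Worked example

```r
library(uhdrdosim)

# 1. simulate a recombination campaign for a Markus-type chamber
campaign <- default_campaign("markus_like", seed = 42)
tbl <- recombination_campaign(campaign, methods = c("two_voltage", "linear", "niatel"))
head(as.data.frame(tbl)[, c("dose_rate_gy_s", "method", "ks", "u_ks")], 6)
#>   dose_rate_gy_s      method     ks       u_ks
#> 1            5.1 two_voltage 1.0007 5.7648e-05
#> 2            5.1      linear 1.0005 2.1357e-05
#> 3            5.1      niatel 1.0015 4.2180e-04
#> 4           10.6 two_voltage 1.0011 3.9161e-05
#> 5           10.6      linear 1.0010 2.2141e-05
#> 6           10.6      niatel 1.0017 2.7452e-04

# 2. dose to water from a chamber reading at the highest dose rate
mk <- chamber_spec("advanced_markus", nd_w = 1.521, electrode_gap = 1.0)
ks <- ks_at(fit_niatel(campaign[[7]]), 300)
ks
#> <ks_result> niatel @ 300 V: ks = 1.006198 +/- 0.00051 (f = 0.9938)
reading <- chamber_reading(5.030, temperature = 21.3, pressure = 100.8, field_id = "5x6")
dose_to_water(reading, mk, ks = ks, k_q = 1.0, u_rel_m = 0.007, u_rel_kq = 0.021)
#> <dose_result> advanced_markus field 5x6: 7.7724 +/- 0.1721 Gy  [k_tp 1.0097, k_pol 1.0000, k_s 1.0062, k_q 1.0000]

# 3. calorimeter reference: 20 simulated quasi-adiabatic runs at 7.702 Gy
spec <- calorimeter_spec(specific_heat = 710, s_w_g = 1.125, k_fl = 0.999)
campaign_dose(simulate_calorimeter_campaign(7.702, spec, n_runs = 20, seed = 42), spec)
#> <calorimeter_dose_result> 20 runs: 7.7026 Gy (SDOM 0.0009, type B 0.1155, combined 0.1155)

# 4. chamber vs calorimeter over the six shipped campaign fields
cal <- uhdr_table("calorimeter_doses")[, c("field_id", "dose_gy")]
ch  <- uhdr_table("chamber_doses")
mkd <- ch[ch$chamber == "advanced_markus", c("field_id", "dose_gy", "sdom_gy")]
names(mkd)[3] <- "u_gy"
cat(format_comparison_report(compare_doses(mkd, cal)), sep = "\n")
#> field    chamber (Gy) calorimeter (Gy)    ratio
#> 5x6             7.694            7.654    1.005
#> 5x8             7.710            7.690    1.003
#> 5x10            7.769            7.726    1.006
#> 5x12            7.701            7.736    0.995
#> 6x5             7.685            7.666    1.002
#> 12x5            7.746            7.741    1.001
#> average ratio: 1.002 +/- 0.007 (n = 6)
#> agreement z = 0.07 (not significant at threshold 1.5)
```

Reading the numbers: k_s at the 300 V operating voltage grows from ~1.001
to ~1.006 as the dose rate rises from 5 to 62 Gy/s — a ≤0.6 % correction,
so the chamber remains usable at FLASH dose rates. The chamber dose for the
~7.7 Gy field carries a ~2.2 % relative uncertainty dominated by the beam
quality conversion factor, the calorimeter mean is dominated by its 1.5 %
type-B budget, and the 1.002 average dose ratio differs from unity by far
less than the combined systematic uncertainty (z = 0.07).

A thin command-line front end wraps the same drivers:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","uhdrdosim.R", package="uhdrdosim"))') \
    simulate --archetype markus_like --seed 1 --out campaign/
```

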