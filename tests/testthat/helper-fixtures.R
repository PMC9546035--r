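# noise-free series exactly on a given saturation model
exact_series <- function(Qp, a = 0, kc = 0, gamma = 0,
                         voltages = c(50, 100, 200, 300, 400),
                         dose_rate = 10, label = "exact") {
  inv <- (1 / Qp + (a / Qp) / voltages + kc / voltages^2) * exp(-gamma * voltages)
  charge_voltage_series(label, dose_rate, voltages, 1 / inv)
}

table1_dose_rates <- c(5.1, 10.6, 19.5, 30.8, 40.2, 52.1, 61.7)
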