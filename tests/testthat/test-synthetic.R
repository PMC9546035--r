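test_that("seeded generation is deterministic and seed-sensitive", {
  tr <- chamber_truth(5.03, 0.2, 1.6, 0, 0.001, "mk")
  a <- simulate_charge_series(tr, 30.8, n_repeats = 5, seed = 123)
  b <- simulate_charge_series(tr, 30.8, n_repeats = 5, seed = 123)
  c <- simulate_charge_series(tr, 30.8, n_repeats = 5, seed = 124)
  expect_identical(a$charge_mean, b$charge_mean)
  expect_identical(attr(a, "repeat_charges"), attr(b, "repeat_charges"))
  expect_false(identical(a$charge_mean, c$charge_mean))
  # generation does not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(3)
  set.seed(7); invisible(simulate_charge_series(tr, 10, seed = 5))
  expect_identical(rnorm(3), before)
})

test_that("noise-free generation closes against every matching fit to 1e-8", {
  # each forward model recovered by its own fit
  tr_lin <- chamber_truth(5.0, 0, 100 / 20, 0, 0)
  f <- fit_linear(simulate_charge_series(tr_lin, 20, n_repeats = 1, seed = 1))
  expect_equal(f$Qp, 5.0, tolerance = 1e-10)
  expect_equal(f$kc, 100, tolerance = 1e-8)

  tr_nia <- chamber_truth(5.0, 0.5, 100 / 20, 0, 0)
  fn <- fit_niatel(simulate_charge_series(tr_nia, 20, n_repeats = 1, seed = 1))
  expect_equal(fn$Qp, 5.0, tolerance = 1e-9)
  expect_equal(fn$a, 0.5, tolerance = 1e-7)

  tr_cm <- chamber_truth(12.60, 0.4, 40 / 20, 1e-4, 0)
  fc <- fit_niatel_cm(simulate_charge_series(tr_cm, 20,
                                             voltages = seq(50, 400, 50),
                                             n_repeats = 1, seed = 1))
  expect_equal(fc$Qp, 12.60, tolerance = 1e-8)
  expect_equal(fc$gamma, 1e-4, tolerance = 1e-6)
})

test_that("generated ks matches the closed-form forward model", {
  # Qp 5.03, a 0.2, kc 1.6/(Gy/s) at 61.7 Gy/s and 300 V
  tr <- chamber_truth(5.03, 0.2, 1.6, 0, 0)
  s <- simulate_charge_series(tr, 61.7, n_repeats = 1, seed = 1)
  f <- fit_niatel(s)
  expected <- 1 + 0.2 / 300 + 5.03 * (1.6 * 61.7) / 300^2   # ~1.0062
  expect_equal(ks_at(f, 300)$ks, expected, tolerance = 1e-8)
  expect_equal(expected, 1.0062, tolerance = 2e-4)
})

test_that("two-voltage ks minus one is proportional to dose rate when kc scales linearly", {
  tr <- chamber_truth(5.03, a_true = 0, kc_per_doserate = 1.6,
                      gamma_true = 0, noise_rel_sd = 0)
  ks <- vapply(table1_dose_rates, function(d) {
    s <- simulate_charge_series(tr, d, n_repeats = 1, seed = 1)
    ks_two_voltage(s$charge_mean[s$voltage == 300],
                   s$charge_mean[s$voltage == 100], 300, 100)$ks
  }, 0)
  expect_true(all(diff(ks) > 0))
  fit <- lm(I(ks - 1) ~ 0 + table1_dose_rates)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("markus-like archetype spans the expected two-voltage ks range at 300 V", {
  campaign <- default_campaign("markus_like", seed = 21, noise_rel_sd = 0)
  tbl <- recombination_campaign(campaign, methods = "two_voltage")
  expect_equal(nrow(tbl), 7L)
  expect_true(all(diff(tbl$ks[order(tbl$dose_rate_gy_s)]) > 0))
  expect_gt(min(tbl$ks), 1.0003)
  expect_lt(max(tbl$ks), 1.008)
  expect_gt(max(tbl$ks) - min(tbl$ks), 0.003)  # visible dose-rate slope
})

test_that("ppc05-like archetype is flat in dose rate and underestimates Qp by 3V linear", {
  campaign <- default_campaign("ppc05_like", seed = 22, noise_rel_sd = 0,
                               voltages = seq(50, 400, 50))
  tbl <- recombination_campaign(campaign,
                                methods = c("two_voltage",
                                            "three_voltage_linear",
                                            "niatel_cm"))
  tv <- tbl[tbl$method == "two_voltage", ]
  expect_lt(max(tv$ks) - min(tv$ks), 0.003)  # variation <= 0.3 %
  # curve-fit saturation charge exceeds the three-voltage linear estimate
  for (d in unique(tbl$dose_rate_gy_s)) {
    q3 <- tbl$Qp_nc[tbl$method == "three_voltage_linear" &
                      tbl$dose_rate_gy_s == d]
    qc <- tbl$Qp_nc[tbl$method == "niatel_cm" & tbl$dose_rate_gy_s == d]
    expect_gt(qc, q3)
  }
  # total correction below unity at the lowest dose rates (charge gain wins)
  cm <- tbl[tbl$method == "niatel_cm", ]
  expect_true(cm$below_unity[which.min(cm$dose_rate_gy_s)])
  expect_false(cm$below_unity[which.max(cm$dose_rate_gy_s)])
  expect_error(default_campaign("farmer_like"))
})

test_that("noisy three-voltage linear underestimates the charge-multiplication Qp", {
  campaign <- default_campaign("ppc05_like", seed = 31,
                               voltages = seq(50, 400, 50))
  diffs <- vapply(campaign, function(s) {
    fit_niatel_cm(s)$Qp - fit_linear(s, voltage_subset = c(50, 100, 200))$Qp
  }, 0)
  expect_gt(mean(diffs), 0)  # campaign-level sign of the Qp difference
})

test_that("calorimeter trace generator closes against the campaign analysis", {
  spec <- calorimeter_spec(710, 1.125, 0.999)
  runs <- replicate(5, simulate_calorimeter_run(7.702, spec), simplify = FALSE)
  res <- suppressWarnings(campaign_dose(runs, spec))
  expect_equal(res$mean_dose_w, 7.702, tolerance = 1e-10)
  runs2 <- simulate_calorimeter_campaign(7.702, spec, n_runs = 20,
                                         run_scatter_rel = 4e-4, seed = 9)
  res2 <- campaign_dose(runs2, spec)
  expect_lt(abs(res2$mean_dose_w - 7.702), 3 * res2$sdom)
})
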