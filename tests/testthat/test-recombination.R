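test_that("two-voltage technique matches direct evaluation of the quadratic formula", {
  # equal charges force saturation
  r0 <- ks_two_voltage(10.0, 10.0, 300, 100)
  expect_identical(r0$ks, 1.0)
  expect_identical(r0$collection_efficiency * r0$ks, 1.0)
  # hand-evaluated cases at the protocol ratio 3: ks = 8 / (9 - Q1/Q2)
  cases <- list(c(10.00, 9.90), c(10.00, 9.50))
  for (qq in cases) {
    expected <- 8 / (9 - qq[1] / qq[2])
    expect_equal(ks_two_voltage(qq[1], qq[2], 300, 100)$ks, expected,
                 tolerance = 1e-12)
  }
  expect_equal(ks_two_voltage(10.00, 9.90, 300, 100)$ks, 1.00126,
               tolerance = 1e-5)
  expect_equal(ks_two_voltage(10.00, 9.50, 300, 100)$ks, 1.00662,
               tolerance = 1e-5)
})

test_that("two-voltage technique guards its domain", {
  expect_error(ks_two_voltage(-1, 5, 300, 100), class = "uhdr_domain_error")
  expect_error(ks_two_voltage(5, 5, 100, 300), class = "uhdr_domain_error")
  # Q1/Q2 >= (V1/V2)^2 is an inverted saturation curve
  expect_error(ks_two_voltage(90, 5, 300, 100), class = "uhdr_degenerate_error")
  expect_warning(ks_two_voltage(10, 9.9, 400, 100), "ratio")
  # uncertainty propagation: equal-relative-u charges
  r <- ks_two_voltage(10, 9.9, 300, 100, u_Q1 = 0.01, u_Q2 = 0.01)
  expect_gt(r$u_ks, 0)
})

test_that("linear extrapolation recovers an exact Boag-model series", {
  s <- exact_series(5.000, kc = 100)
  f <- fit_linear(s)
  expect_equal(f$model, "linear")
  expect_equal(f$Qp, 5.000, tolerance = 1e-10)
  expect_equal(f$kc, 100, tolerance = 1e-8)
  expect_lt(f$residual, 1e-12)
})

test_that("voltage subsets select the three-voltage linear method", {
  s <- exact_series(5.000, kc = 100)
  f3 <- fit_linear(s, voltage_subset = c(50, 100, 200))
  expect_equal(f3$model, "three_voltage_linear")
  expect_equal(f3$Qp, 5.000, tolerance = 1e-10)
  expect_setequal(f3$voltages_used, c(50, 100, 200))
  expect_error(fit_linear(s, voltage_subset = c(50, 150)),
               class = "uhdr_input_error")
})

test_that("non-positive extrapolated intercept raises an extrapolation failure", {
  # 1/Qc decreasing so steeply that the intercept goes negative
  s <- charge_voltage_series("bad", 10, c(100, 200),
                             c(1, 100), charge_se = 0)
  expect_error(suppressWarnings(fit_linear(s)),
               class = "uhdr_extrapolation_error")
})

test_that("negative volume-recombination slope is clamped to zero with a warning", {
  # charge *decreasing* toward saturation: unphysical kc < 0
  v <- c(50, 100, 200, 300, 400)
  q <- 1 / (1 / 5 - 20 / v^2)
  s <- suppressWarnings(charge_voltage_series("neg", 10, v, q))
  expect_warning(f <- fit_linear(s), "kc")
  expect_identical(f$kc, 0)
  expect_true(f$constraint_bound)
})

test_that("Niatel quadratic fit recovers its exact forward model", {
  s <- exact_series(5.000, a = 0.5, kc = 100)
  f <- fit_niatel(s)
  expect_equal(f$Qp, 5.000, tolerance = 1e-9)
  expect_equal(f$a, 0.5, tolerance = 1e-7)
  expect_equal(f$kc, 100, tolerance = 1e-7)
  # a = 0 reduces to the linear solution
  s0 <- exact_series(5.000, a = 0, kc = 100)
  fn <- fit_niatel(s0)
  fl <- fit_linear(s0)
  expect_equal(fn$Qp, fl$Qp, tolerance = 1e-9)
  expect_lt(abs(fn$a), 1e-7)
  expect_error(fit_niatel(exact_series(5, kc = 100, voltages = c(100, 300))),
               class = "uhdr_input_error")
})

test_that("charge-multiplication fit recovers all four parameters exactly", {
  s <- exact_series(12.60, a = 0.4, kc = 40, gamma = 1.0e-4,
                    voltages = seq(50, 400, by = 50))
  f <- fit_niatel_cm(s)
  expect_equal(f$Qp, 12.60, tolerance = 1e-8)
  expect_equal(f$a, 0.4, tolerance = 1e-6)
  expect_equal(f$kc, 40, tolerance = 1e-6)
  expect_equal(f$gamma, 1.0e-4, tolerance = 1e-6)
  expect_lt(f$residual, 1e-12)
  expect_error(fit_niatel_cm(exact_series(5, kc = 10, voltages = c(50, 100, 200))),
               class = "uhdr_input_error")
})

test_that("gamma = 0 data reduce the charge-multiplication fit to the Niatel fit", {
  s <- exact_series(5.000, a = 0.3, kc = 80)
  fcm <- fit_niatel_cm(s)
  fn <- fit_niatel(s)
  expect_lt(abs(fcm$gamma), 1e-7)
  expect_equal(fcm$Qp, fn$Qp, tolerance = 1e-6)
})

test_that("ks_at evaluates each model's closed form with reciprocity", {
  fl <- fit_linear(exact_series(5.000, kc = 100))
  k <- ks_at(fl, 300)
  expect_equal(k$ks, 1 + 100 * 5 / 300^2, tolerance = 1e-10)  # 1.00556
  expect_identical(k$collection_efficiency, 1 / k$ks)
  expect_false(k$below_validity_bound)
  # asymptotic saturation
  expect_equal(ks_at(fl, 1e9)$ks, 1, tolerance = 1e-9)
  expect_error(ks_at(fl, -5), class = "uhdr_domain_error")

  fn <- fit_niatel(exact_series(5.000, a = 0.5, kc = 100))
  expect_equal(ks_at(fn, 300)$ks, 1 + 0.5 / 300 + 100 * 5 / 9e4,
               tolerance = 1e-8)
})

test_that("pure charge multiplication yields a flagged below-unity total correction", {
  s <- exact_series(5.000, a = 0, kc = 1e-9, gamma = 1e-4,
                    voltages = seq(50, 400, 50))
  f <- fit_niatel_cm(s)
  k <- ks_at(f, 300)
  expect_equal(k$ks, exp(-0.03), tolerance = 1e-4)  # ~0.97045
  expect_equal(k$ks_cm, exp(-0.03), tolerance = 1e-4)
  expect_true(k$below_unity)
  # recombination-only factor recoverable as total / ks_cm
  expect_equal(k$ks / k$ks_cm, 1, tolerance = 1e-6)
})

test_that("two-voltage and linear-fit ks agree analytically on exact-model data", {
  # the identity holds for any (Qp, kc, V1, V2) when data sit on the model
  set.seed(42)
  for (i in 1:3) {
    Qp <- runif(1, 2, 20)
    kc <- runif(1, 10, 200)
    s <- exact_series(Qp, kc = kc)
    fl <- fit_linear(s)
    tv <- ks_two_voltage(s$charge_mean[s$voltage == 300],
                         s$charge_mean[s$voltage == 100], 300, 100)
    expect_equal(tv$ks, ks_at(fl, 300)$ks, tolerance = 1e-8)
  }
})

test_that("delta-method ks uncertainty agrees with Monte-Carlo propagation", {
  tr <- chamber_truth(5.03, 0.2, 1.6, 0, 0.001, "mk")
  f <- fit_niatel(simulate_charge_series(tr, 40.2, n_repeats = 5, seed = 11))
  k <- ks_at(f, 300)
  mc <- ks_mc_uncertainty(f, 300, n = 5e4, seed = 2)
  expect_equal(mc$sd, k$u_ks, tolerance = 0.05)
  expect_equal(mc$mean, k$ks, tolerance = 1e-4)
})

test_that("all methods coincide on a noise-free linear-model campaign", {
  s <- exact_series(5.000, kc = 100, dose_rate = 20)
  tbl <- recombination_campaign(list(s),
                                methods = c("two_voltage", "linear", "niatel"))
  expect_equal(nrow(tbl), 3L)
  expect_lt(diff(range(tbl$ks)) / mean(tbl$ks), 1e-6)
  d <- attr(tbl, "method_differences")
  expect_true(all(abs(d$diff_pct) < 1e-4))
})

test_that("campaign table spans dose rates x methods and skips gracefully", {
  tr <- chamber_truth(5.03, 0.2, 1.6, 0, 0.001, "mk")
  campaign <- lapply(c(10, 30), function(d)
    simulate_charge_series(tr, d, n_repeats = 3, seed = round(d)))
  tbl <- recombination_campaign(campaign, methods = c("two_voltage", "linear"))
  expect_equal(nrow(tbl), 4L)
  expect_setequal(unique(tbl$method), c("two_voltage", "linear"))
  # a series without the V_ref/3 point: two-voltage skipped with a warning
  short <- simulate_charge_series(tr, 50, voltages = c(50, 200, 300, 400),
                                  n_repeats = 3, seed = 1)
  expect_warning(
    tbl2 <- recombination_campaign(list(short),
                                   methods = c("two_voltage", "linear")),
    "skipped")
  expect_equal(tbl2$method, "linear")
  expect_error(recombination_campaign(campaign, methods = "bogus"),
               class = "uhdr_input_error")
})

test_that("ks at fixed voltage rises monotonically with dose rate when kc scales with it", {
  tr <- chamber_truth(5.03, a_true = 0, kc_per_doserate = 1.6, gamma_true = 0,
                      noise_rel_sd = 0)
  campaign <- lapply(table1_dose_rates, function(d)
    simulate_charge_series(tr, d, n_repeats = 1, seed = 1))
  tbl <- recombination_campaign(campaign, methods = "linear")
  expect_true(all(diff(tbl$ks[order(tbl$dose_rate_gy_s)]) > 0))
})
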