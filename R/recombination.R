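#' @importFrom stats coef lm sd setNames
NULL

.err <- function(msg, class) stop(errorCondition(msg, class = c(class, "uhdr_error")))

# transform charge (nC) to the 1/Q scale used by all extrapolation fits;
# first-order propagation of the charge SE: u(1/Q) = u(Q)/Q^2
.inv_charge <- function(series) {
  q <- series$charge_mean
  list(v = series$voltage, y = 1 / q, u_y = series$charge_se / q^2)
}

# weighted least squares with known observation variances.
# When weights come from measurement SEs the parameter covariance is
# (X'WX)^-1 inflated by the Birge ratio max(1, chi^2/dof) so that
# underestimated observation variances (few repeats) do not yield
# overconfident parameter uncertainties; in the unweighted fallback it is
# sigma^2 (X'X)^-1.
.wls <- function(X, y, u_y) {
  weighted <- any(u_y > 0)
  if (weighted && any(u_y <= 0)) {
    # guard against a zero-SE point dominating: floor at the smallest nonzero SE
    u_y[u_y <= 0] <- min(u_y[u_y > 0])
  }
  w <- if (weighted) 1 / u_y^2 else rep(1, length(y))
  XtW <- t(X * w)
  A <- XtW %*% X
  beta <- drop(solve(A, XtW %*% y))
  res <- drop(y - X %*% beta)
  df <- length(y) - ncol(X)
  if (weighted) {
    birge <- if (df > 0) max(1, sum(w * res^2) / df) else 1
    cov <- birge * solve(A)
  } else {
    s2 <- if (df > 0) sum(res^2) / df else 0
    cov <- s2 * solve(A)
  }
  list(coef = beta, cov = cov, residuals = res,
       rms = sqrt(mean(res^2)), weighted = weighted)
}

# assemble the canonical 4-parameter representation on the 1/Q scale:
# 1/Qc = (b0 + b1/V + b2/V^2) * exp(-g*V),  b0 = 1/Qp, b1 = a/Qp, b2 = kc
.new_fit <- function(model, b, cov4, series, voltages_used, rms,
                     constraint_bound = FALSE) {
  b0 <- b[1]
  if (!is.finite(b0) || b0 <= 0)
    .err("extrapolated intercept <= 0: saturation charge undefined",
         "uhdr_extrapolation_error")
  Qp <- 1 / b0
  u_Qp <- sqrt(cov4[1, 1]) / b0^2
  a <- b[2] / b0
  # delta method for a = b1/b0
  ga <- c(-b[2] / b0^2, 1 / b0, 0, 0)
  u_a <- sqrt(max(0, drop(t(ga) %*% cov4 %*% ga)))
  structure(list(
    model = model, Qp = Qp, u_Qp = u_Qp,
    kc = b[3], u_kc = sqrt(cov4[3, 3]),
    a = a, u_a = u_a,
    gamma = b[4], u_gamma = sqrt(cov4[4, 4]),
    coef = setNames(b, c("b0", "b1", "b2", "gamma")), cov = cov4,
    voltages_used = voltages_used, residual = rms,
    chamber_id = attr(series, "chamber_id"),
    dose_rate = attr(series, "dose_rate"),
    constraint_bound = constraint_bound),
    class = "recombination_fit")
}

#' @export
print.recombination_fit <- function(x, ...) {
  cat(sprintf("<recombination_fit> model %s (chamber %s, %g Gy/s)\n",
              x$model, x$chamber_id %||% "?", x$dose_rate %||% NA))
  cat(sprintf("  Qp = %.6g +/- %.3g nC\n", x$Qp, x$u_Qp))
  if (x$model != "two_voltage")
    cat(sprintf("  kc = %.6g +/- %.3g nC^-1 V^2\n", x$kc, x$u_kc))
  if (x$model %in% c("niatel", "niatel_cm"))
    cat(sprintf("  a  = %.6g +/- %.3g V\n", x$a, x$u_a))
  if (x$model == "niatel_cm")
    cat(sprintf("  gamma = %.6g +/- %.3g V^-1\n", x$gamma, x$u_gamma))
  cat(sprintf("  rms residual (1/Q scale): %.3g, voltages: %s\n",
              x$residual, paste(x$voltages_used, collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.new_ks_result <- function(ks, u_ks, voltage, method, ks_cm = 1) {
  structure(list(ks = ks, u_ks = u_ks, ks_cm = ks_cm,
                 collection_efficiency = 1 / ks, voltage = voltage,
                 method = method,
                 below_validity_bound = (1 / ks) < 0.7,
                 below_unity = ks < 1),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> %s @ %g V: ks = %.6f +/- %.2g (f = %.4f%s%s)\n",
              x$method, x$voltage, x$ks, x$u_ks, x$collection_efficiency,
              if (x$below_validity_bound) ", f < 0.7!" else "",
              if (x$below_unity) ", below unity" else ""))
  invisible(x)
}

#' Two-voltage ion-recombination correction (continuous beam)
#'
#' The recombination correction factor at the operating voltage `V1` from
#' charges collected at two bias voltages, using the continuous-beam quadratic
#' expression
#' \deqn{k_s = \frac{(V_1/V_2)^2 - 1}{(V_1/V_2)^2 - Q_1/Q_2},}
#' the method recommended by the TRS-398 and TG-51 protocols. The protocol
#' voltage ratio is 3 (e.g. 300 V / 100 V); other ratios are accepted with a
#' warning. The uncertainty is first-order propagation of the charge
#' uncertainties.
#'
#' @param Q1,Q2 Collected charge (nC) at `V1` and `V2`; both > 0.
#' @param V1,V2 Bias voltages in V with `V1 > V2 > 0`.
#' @param u_Q1,u_Q2 Standard uncertainties of the charges (nC), default 0.
#' @return A `ks_result` with fields `ks`, `u_ks`, `collection_efficiency`
#'   (= 1/ks, exactly reciprocal), `voltage` (= `V1`), `method`, and flags
#'   `below_validity_bound` (collection efficiency < 0.7, outside the stated
#'   validity of the continuous-beam formula) and `below_unity`.
#' @examples
#' ks_two_voltage(10.0, 9.9, 300, 100)
#' @export
ks_two_voltage <- function(Q1, Q2, V1, V2, u_Q1 = 0, u_Q2 = 0) {
  if (!all(is.finite(c(Q1, Q2, V1, V2))) || Q1 <= 0 || Q2 <= 0 || V2 <= 0)
    .err("charges and voltages must be positive", "uhdr_domain_error")
  if (V1 <= V2)
    .err("two-voltage method requires V1 > V2", "uhdr_domain_error")
  r <- V1 / V2
  if (abs(r - 3) > 1e-6)
    warning(sprintf("voltage ratio V1/V2 = %.4g differs from the protocol ratio 3", r),
            call. = FALSE)
  q <- Q1 / Q2
  D <- r^2 - q
  if (D <= 0)
    .err("degenerate measurement: Q1/Q2 >= (V1/V2)^2, saturation curve inverted",
         "uhdr_degenerate_error")
  ks <- (r^2 - 1) / D
  # dks/dQ1 = (r^2-1)/D^2 * 1/Q2 ; dks/dQ2 = -(r^2-1)/D^2 * Q1/Q2^2
  dk <- (r^2 - 1) / D^2
  u_ks <- dk * sqrt((u_Q1 / Q2)^2 + (u_Q2 * Q1 / Q2^2)^2)
  .new_ks_result(ks, u_ks, V1, "two_voltage")
}

.match_voltages <- function(series, wanted) {
  idx <- match(round(wanted, 1), round(series$voltage, 1))
  if (anyNA(idx))
    .err(sprintf("requested voltage(s) %s not present in series",
                 paste(wanted[is.na(idx)], collapse = ", ")),
         "uhdr_input_error")
  idx
}

#' Linear (Boag) saturation-curve extrapolation
#'
#' Weighted least-squares fit of \eqn{1/Q_c = 1/Q_p + k_c/V^2}: in a
#' continuous beam with volume recombination dominating, the inverse collected
#' charge is linear in the inverse square of the bias voltage, and the
#' saturation charge \eqn{Q_p} is the reciprocal of the extrapolated
#' intercept. With `voltage_subset` of exactly three voltages this is the
#' three-voltage linear method used when charge multiplication distorts the
#' high-voltage readings (restrict the fit to the linear low-voltage region).
#'
#' Weights are the inverse variances of \eqn{1/Q_c} obtained by first-order
#' transformation of the charge standard errors; when all SEs are zero the
#' fit is unweighted. The physical constraint \eqn{k_c \ge 0} is enforced:
#' if the unconstrained slope is negative the fit is repeated with
#' \eqn{k_c = 0} and a warning reports the unconstrained estimate.
#'
#' @param series A [charge_voltage_series()].
#' @param voltage_subset Optional voltages (V) to restrict the fit to; every
#'   requested voltage must exist in the series (matched at 0.1 V
#'   resolution).
#' @return A `recombination_fit` with `model` `"linear"` (or
#'   `"three_voltage_linear"` when a subset of exactly 3 voltages was used),
#'   `Qp`/`u_Qp` (nC), `kc`/`u_kc` (nC^-1 V^2), the coefficient covariance
#'   and the rms residual on the 1/Q scale.
#' @export
fit_linear <- function(series, voltage_subset = NULL) {
  stopifnot(inherits(series, "charge_voltage_series"))
  sub <- series
  if (!is.null(voltage_subset)) {
    idx <- .match_voltages(series, voltage_subset)
    sub <- series[idx, , drop = FALSE]
    attributes(sub)[c("chamber_id", "dose_rate", "polarity", "class")] <-
      attributes(series)[c("chamber_id", "dose_rate", "polarity", "class")]
  }
  if (nrow(sub) < 2L)
    .err("linear extrapolation needs at least 2 distinct voltages",
         "uhdr_input_error")
  tr <- .inv_charge(sub)
  X <- cbind(1, 1 / tr$v^2)
  f <- .wls(X, tr$y, tr$u_y)
  constraint_bound <- FALSE
  if (f$coef[2] < 0) {
    warning(sprintf(
      "unconstrained kc = %.4g < 0; refitting with kc = 0 (physical charge loss)",
      f$coef[2]), call. = FALSE)
    u_kc_unc <- sqrt(f$cov[2, 2])
    f <- .wls(cbind(1, rep(0, length(tr$y)))[, 1, drop = FALSE], tr$y, tr$u_y)
    f$coef <- c(f$coef, 0)
    f$cov <- rbind(cbind(f$cov, 0), c(0, u_kc_unc^2))
    constraint_bound <- TRUE
  }
  model <- if (!is.null(voltage_subset) && length(voltage_subset) == 3L)
    "three_voltage_linear" else "linear"
  b <- c(f$coef[1], 0, f$coef[2], 0)
  cov4 <- matrix(0, 4, 4)
  cov4[c(1, 3), c(1, 3)] <- f$cov
  .new_fit(model, b, cov4, series, sub$voltage, f$rms,
           constraint_bound = constraint_bound)
}

#' Niatel quadratic saturation-curve extrapolation
#'
#' Weighted fit of \eqn{1/Q_c = 1/Q_p + (a/Q_p)/V + k_c/V^2}, combining
#' Jaffe initial recombination (the \eqn{1/V} term, chamber parameter `a`)
#' with Boag volume recombination (the \eqn{1/V^2} term) for continuous
#' beams. Requires at least three distinct voltages. The constraint
#' \eqn{k_c \ge 0} is enforced as in [fit_linear()].
#'
#' @param series A [charge_voltage_series()].
#' @return A `recombination_fit` with `model = "niatel"` carrying `Qp`, `a`
#'   (V) and `kc` with uncertainties from the fit covariance combined with
#'   the charge standard errors.
#' @export
fit_niatel <- function(series) {
  stopifnot(inherits(series, "charge_voltage_series"))
  if (nrow(series) < 3L)
    .err("Niatel quadratic fit needs at least 3 distinct voltages",
         "uhdr_input_error")
  tr <- .inv_charge(series)
  X <- cbind(1, 1 / tr$v, 1 / tr$v^2)
  f <- .wls(X, tr$y, tr$u_y)
  constraint_bound <- FALSE
  if (f$coef[3] < 0) {
    warning(sprintf(
      "unconstrained kc = %.4g < 0; refitting with kc = 0 (physical charge loss)",
      f$coef[3]), call. = FALSE)
    u_kc_unc <- sqrt(f$cov[3, 3])
    f2 <- .wls(X[, 1:2, drop = FALSE], tr$y, tr$u_y)
    f2$coef <- c(f2$coef, 0)
    f2$cov <- rbind(cbind(f2$cov, 0), c(0, 0, u_kc_unc^2))
    f <- f2
    constraint_bound <- TRUE
  }
  b <- c(f$coef[1], f$coef[2], f$coef[3], 0)
  cov4 <- matrix(0, 4, 4)
  cov4[1:3, 1:3] <- f$cov
  .new_fit("niatel", b, cov4, series, series$voltage, f$rms,
           constraint_bound = constraint_bound)
}

#' Semiempirical charge-multiplication saturation-curve fit
#'
#' Nonlinear weighted fit of
#' \deqn{1/Q_c = \left(1/Q_p + (a/Q_p)/V + k_c/V^2\right)\,e^{-\gamma V},}
#' the Niatel model augmented with an exponential charge-multiplication
#' factor: near saturation small-gap chambers can collect *excess*
#' (non-dosimetric) charge from multiplication in the high electric field,
#' which depresses \eqn{1/Q_c} at high voltage and breaks both the linear and
#' quadratic extrapolations. \eqn{\gamma} (V^-1) quantifies that gain.
#'
#' The fit is Levenberg-Marquardt, initialized from the [fit_niatel()]
#' solution with \eqn{\gamma = 0}, with bounds \eqn{Q_p > 0},
#' \eqn{k_c \ge 0}, \eqn{0 \le \gamma \le 10^{-2}} V^-1, and up to
#' `max_restarts` jittered restarts (deterministic jitter) on
#' non-convergence.
#'
#' @param series A [charge_voltage_series()] with at least 4 distinct
#'   voltages (the model has 4 free parameters).
#' @param max_restarts Maximum number of jittered restarts, default 5.
#' @return A `recombination_fit` with `model = "niatel_cm"` carrying `Qp`,
#'   `a`, `kc`, `gamma` and their covariance.
#' @export
fit_niatel_cm <- function(series, max_restarts = 5L) {
  stopifnot(inherits(series, "charge_voltage_series"))
  if (nrow(series) < 4L)
    .err("charge-multiplication fit needs at least 4 distinct voltages",
         "uhdr_input_error")
  tr <- .inv_charge(series)
  weighted <- any(tr$u_y > 0)
  u_y <- tr$u_y
  if (weighted && any(u_y <= 0)) u_y[u_y <= 0] <- min(u_y[u_y > 0])
  w <- if (weighted) 1 / u_y^2 else rep(1, length(tr$y))

  init <- tryCatch(fit_niatel(series), warning = function(w2) {
    suppressWarnings(fit_niatel(series))
  })
  start0 <- c(b0 = unname(init$coef["b0"]), b1 = unname(init$coef["b1"]),
              b2 = max(unname(init$coef["b2"]), 0), g = 0)
  dat <- data.frame(v = tr$v, y = tr$y)
  lower <- c(b0 = .Machine$double.xmin, b1 = -Inf, b2 = 0, g = 0)
  upper <- c(b0 = Inf, b1 = Inf, b2 = Inf, g = 1e-2)

  best <- NULL
  best_res <- Inf
  # deterministic jitter factors for restarts, independent of the user RNG
  jit <- matrix(1 + 0.05 * sin(seq_len(4 * max_restarts)), ncol = 4)
  for (k in 0:max_restarts) {
    start <- if (k == 0) start0 else {
      s <- start0 * jit[k, ]
      s["g"] <- 1e-4 * k   # probe nonzero multiplication from restarts
      pmin(pmax(s, lower), upper)
    }
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(y ~ (b0 + b1 / v + b2 / v^2) * exp(-g * v),
                          data = dat, start = as.list(start), weights = w,
                          lower = lower, upper = upper,
                          control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(w * stats::residuals(fit)^2)
      if (rss < best_res) { best <- fit; best_res <- rss }
      if (k == 0) break   # converged from the Niatel start: accept
    }
  }
  if (is.null(best))
    .err(sprintf("charge-multiplication fit failed to converge after %d restarts (best residual %g)",
                 max_restarts, best_res), "uhdr_fit_error")

  b <- coef(best)
  s <- summary(best)
  # vcov from nls is (chi^2/dof) * (J'WJ)^-1; with weights from known
  # measurement variances keep the chi^2/dof (Birge) inflation only when it
  # exceeds 1, as in the linear fits
  cov <- tryCatch(stats::vcov(best), error = function(e) matrix(NA, 4, 4))
  if (weighted && all(is.finite(cov)) && s$sigma < 1) cov <- cov / s$sigma^2
  rms <- sqrt(mean(stats::residuals(best)^2))
  .new_fit("niatel_cm", c(b[["b0"]], b[["b1"]], b[["b2"]], b[["g"]]),
           cov, series, tr$v, rms)
}

#' Recombination correction factor from a fitted saturation model
#'
#' Evaluates the fitted model at a bias voltage:
#' \itemize{
#'   \item linear / three-voltage linear: \eqn{k_s = 1 + k_c Q_p / V^2};
#'   \item Niatel: \eqn{k_s = 1 + a/V + k_c Q_p/V^2};
#'   \item charge-multiplication model: the *total* correction
#'     \eqn{k_s k_{s,CM} = (1 + a/V + k_c Q_p/V^2)\, e^{-\gamma V}} is
#'     returned in `ks`, with the multiplication factor
#'     \eqn{k_{s,CM} = e^{-\gamma V}} reported separately in `ks_cm` so the
#'     recombination-only factor is `ks / ks_cm`.
#' }
#' A total correction below unity is permitted (charge gain exceeding
#' recombination loss) and flagged via `below_unity`. Uncertainty is
#' first-order (delta-method) propagation through the fit covariance; see
#' [ks_mc_uncertainty()] for a Monte-Carlo cross-check.
#'
#' @param fit A `recombination_fit`.
#' @param V Bias voltage in V (> 0).
#' @return A `ks_result`; `collection_efficiency` is exactly `1/ks`.
#' @export
ks_at <- function(fit, V) {
  stopifnot(inherits(fit, "recombination_fit"))
  if (!is.finite(V) || V <= 0)
    .err("voltage must be positive", "uhdr_domain_error")
  b <- fit$coef
  b0 <- b[["b0"]]; b1 <- b[["b1"]]; b2 <- b[["b2"]]; g <- b[["gamma"]]
  S <- 1 + b1 / (b0 * V) + b2 / (b0 * V^2)
  dS <- c(-(b1 / V + b2 / V^2) / b0^2, 1 / (b0 * V), 1 / (b0 * V^2), 0)
  if (fit$model == "niatel_cm") {
    E <- exp(-g * V)
    ks <- S * E
    grad <- c(E * dS[1:3], -V * S * E)
    ks_cm <- E
  } else {
    ks <- S
    grad <- dS
    ks_cm <- 1
  }
  u_ks <- sqrt(max(0, drop(t(grad) %*% fit$cov %*% grad)))
  .new_ks_result(ks, u_ks, V, fit$model, ks_cm = ks_cm)
}

#' Monte-Carlo propagation of the ks uncertainty
#'
#' Cross-check for the delta-method uncertainty of [ks_at()]: draws fit
#' parameters from a multivariate normal with the fit covariance, evaluates
#' ks for each draw, and returns the empirical mean and SD.
#'
#' @param fit A `recombination_fit`.
#' @param V Bias voltage (V).
#' @param n Number of draws, default `1e5`.
#' @param seed RNG seed for reproducibility.
#' @return A list with `mean`, `sd` and `n`.
#' @export
ks_mc_uncertainty <- function(fit, V, n = 1e5, seed = 1L) {
  stopifnot(inherits(fit, "recombination_fit"))
  free <- which(diag(fit$cov) > 0)
  if (!length(free)) return(list(mean = ks_at(fit, V)$ks, sd = 0, n = n))
  cv <- fit$cov[free, free, drop = FALSE]
  L <- tryCatch(chol(cv), error = function(e) {
    eg <- eigen(cv, symmetric = TRUE)
    t(eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(cv)) %*% t(eg$vectors))
  })
  draws <- local_seed(seed, matrix(stats::rnorm(n * length(free)), n) %*% L)
  th <- matrix(rep(fit$coef, each = n), n)
  th[, free] <- th[, free] + draws
  S <- 1 + th[, 2] / (th[, 1] * V) + th[, 3] / (th[, 1] * V^2)
  ks <- if (fit$model == "niatel_cm") S * exp(-th[, 4] * V) else S
  ks <- ks[is.finite(ks)]
  list(mean = mean(ks), sd = sd(ks), n = length(ks))
}

#' Run every requested ks method over a dose-rate campaign
#'
#' Applies the selected saturation-curve methods to each
#' charge-voltage series of a campaign (one series per dose rate, same
#' chamber) and evaluates the recombination correction at the reference
#' voltage, producing a tidy table of ks versus dose rate per method --
#' the standard summary plot of a recombination study.
#'
#' For the two-voltage technique the series must contain points at `v_ref`
#' and `v_ref/3` (matched at 0.1 V); a series lacking them is skipped with a
#' warning rather than failing the campaign.
#'
#' @param series_list List of [charge_voltage_series()] from one chamber.
#' @param methods Subset of `c("two_voltage", "linear",
#'   "three_voltage_linear", "niatel", "niatel_cm")`.
#' @param v_ref Reference (operating) voltage in V, default 300.
#' @param three_voltage_subset Voltages of the three-voltage linear method,
#'   default `c(50, 100, 200)`.
#' @param keep_going If `TRUE`, a failing fit skips that (series, method)
#'   cell with a warning instead of aborting the campaign.
#' @return A data frame of class `ks_campaign` with one row per
#'   (dose rate, method): `chamber_id`, `dose_rate_gy_s`, `method`,
#'   `voltage_v`, `ks`, `u_ks`, `ks_cm`, `collection_efficiency`, `Qp_nc`,
#'   `u_Qp_nc`, and logical flags. Pairwise percent differences between
#'   methods are attached as `attr(, "method_differences")` (see
#'   [method_differences()]).
#' @export
recombination_campaign <- function(series_list,
                                   methods = c("two_voltage", "linear", "niatel"),
                                   v_ref = 300,
                                   three_voltage_subset = c(50, 100, 200),
                                   keep_going = FALSE) {
  supported <- c("two_voltage", "linear", "three_voltage_linear",
                 "niatel", "niatel_cm")
  bad <- setdiff(methods, supported)
  if (length(bad))
    .err(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")),
         "uhdr_input_error")
  chambers <- unique(vapply(series_list, attr, "", "chamber_id"))
  if (length(chambers) != 1L)
    .err("all series in a campaign must come from the same chamber",
         "uhdr_input_error")

  rows <- list()
  for (s in series_list) {
    dr <- attr(s, "dose_rate")
    for (m in methods) {
      res <- tryCatch({
        if (m == "two_voltage") {
          idx <- tryCatch(.match_voltages(s, c(v_ref, v_ref / 3)),
                          error = function(e) NULL)
          if (is.null(idx)) {
            warning(sprintf(
              "series at %g Gy/s lacks %g V and/or %g V; two-voltage method skipped",
              dr, v_ref, v_ref / 3), call. = FALSE)
            NULL
          } else {
            kr <- ks_two_voltage(s$charge_mean[idx[1]], s$charge_mean[idx[2]],
                                 s$voltage[idx[1]], s$voltage[idx[2]],
                                 s$charge_se[idx[1]], s$charge_se[idx[2]])
            list(kr = kr, Qp = NA_real_, u_Qp = NA_real_)
          }
        } else {
          fit <- switch(m,
            linear = fit_linear(s),
            three_voltage_linear = fit_linear(s, voltage_subset = three_voltage_subset),
            niatel = fit_niatel(s),
            niatel_cm = fit_niatel_cm(s))
          list(kr = ks_at(fit, v_ref), Qp = fit$Qp, u_Qp = fit$u_Qp)
        }
      }, error = function(e) {
        if (!keep_going) stop(e)
        warning(sprintf("method %s failed at %g Gy/s: %s", m, dr,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(res)) next
      kr <- res$kr
      rows[[length(rows) + 1L]] <- data.frame(
        chamber_id = chambers, dose_rate_gy_s = dr, method = m,
        voltage_v = kr$voltage, ks = kr$ks, u_ks = kr$u_ks, ks_cm = kr$ks_cm,
        collection_efficiency = kr$collection_efficiency,
        Qp_nc = res$Qp, u_Qp_nc = res$u_Qp,
        below_validity_bound = kr$below_validity_bound,
        below_unity = kr$below_unity)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ks_campaign", "data.frame")
  attr(out, "method_differences") <- method_differences(out)
  out
}

#' Pairwise percent differences between ks methods
#'
#' For each dose rate in a campaign table, the percent difference
#' `100 * (ks_A - ks_B) / ks_B` for every ordered method pair, the quantity
#' used to compare, e.g., the two-voltage technique against the extrapolation
#' methods.
#'
#' @param campaign A `ks_campaign` data frame from
#'   [recombination_campaign()].
#' @return A data frame with columns `dose_rate_gy_s`, `method_a`,
#'   `method_b`, `diff_pct`.
#' @export
method_differences <- function(campaign) {
  stopifnot(is.data.frame(campaign))
  rows <- list()
  for (dr in unique(campaign$dose_rate_gy_s)) {
    sub <- campaign[campaign$dose_rate_gy_s == dr, ]
    ms <- unique(sub$method)
    if (length(ms) < 2L) next
    for (i in seq_along(ms)) for (j in seq_along(ms)) {
      if (i >= j) next
      ka <- sub$ks[sub$method == ms[i]][1]
      kb <- sub$ks[sub$method == ms[j]][1]
      rows[[length(rows) + 1L]] <- data.frame(
        dose_rate_gy_s = dr, method_a = ms[i], method_b = ms[j],
        diff_pct = 100 * (ka - kb) / kb)
    }
  }
  if (!length(rows))
    return(data.frame(dose_rate_gy_s = numeric(), method_a = character(),
                      method_b = character(), diff_pct = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent difference between two saturation-charge estimates
#'
#' `100 * (qp_curve - qp_linear) / qp_linear`, the conventional comparison of
#' a curve-fit (quadratic or charge-multiplication) extrapolation against the
#' linear extrapolation.
#'
#' @param qp_linear,qp_curve Saturation charges (nC) from the linear and the
#'   curve fit.
#' @return Percent difference (positive when the curve fit is higher).
#' @export
qp_percent_difference <- function(qp_linear, qp_curve) {
  if (any(qp_linear <= 0) || any(qp_curve <= 0))
    .err("saturation charges must be positive", "uhdr_domain_error")
  100 * (qp_curve - qp_linear) / qp_linear
}
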