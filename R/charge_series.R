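#' Charge-versus-voltage measurement series
#'
#' Container for the collected charge of an ionization chamber measured at a
#' set of bias voltages under one dose rate and polarity. This is the raw
#' material of every saturation-curve method: the two-voltage technique reads
#' two points off it, the extrapolation fits ([fit_linear()], [fit_niatel()],
#' [fit_niatel_cm()]) use all of it.
#'
#' Charge must be strictly positive and is expected to be non-decreasing in
#' voltage up to measurement noise; a violation beyond three standard errors
#' raises a warning rather than an error, because charge multiplication can
#' legitimately raise high-voltage readings above the saturation plateau.
#'
#' @param chamber_id Character label of the chamber (e.g. `"advanced_markus"`).
#' @param dose_rate Dose rate of the field in Gy/s (a single positive number).
#' @param voltage Numeric vector of bias voltages in V, strictly positive and
#'   pairwise distinct. At least two points are required.
#' @param charge_mean Mean collected charge at each voltage, in nC (> 0).
#' @param charge_se Standard error of the mean charge at each voltage, in nC
#'   (>= 0). Defaults to zero (noise-free / single reading).
#' @param n_repeats Integer number of repeat readings behind each mean
#'   (>= 1). Defaults to 1.
#' @param polarity `"+"` or `"-"`; series are analysed per polarity.
#'
#' @return An object of class `charge_voltage_series`: a data frame with
#'   columns `voltage`, `charge_mean`, `charge_se`, `n_repeats` (sorted by
#'   voltage) and attributes `chamber_id`, `dose_rate`, `polarity`.
#' @seealso [read_charge_csv()] to build series from a measurement file,
#'   [simulate_charge_series()] to generate them from a forward model.
#' @export
charge_voltage_series <- function(chamber_id, dose_rate, voltage, charge_mean,
                                  charge_se = 0, n_repeats = 1L,
                                  polarity = "+") {
  stopifnot(is.character(chamber_id), length(chamber_id) == 1L,
            is.numeric(dose_rate), length(dose_rate) == 1L, dose_rate > 0)
  polarity <- match.arg(polarity, c("+", "-"))
  n <- length(voltage)
  if (n < 2L)
    stop("a charge-voltage series needs at least 2 points", call. = FALSE)
  charge_se <- rep_len(charge_se, n)
  n_repeats <- rep_len(as.integer(n_repeats), n)
  if (length(charge_mean) != n)
    stop("voltage and charge_mean must have the same length", call. = FALSE)
  if (any(!is.finite(voltage)) || any(voltage <= 0))
    stop("voltages must be finite and strictly positive", call. = FALSE)
  if (anyDuplicated(round(voltage, 1)))
    stop("voltages must be pairwise distinct (0.1 V resolution)", call. = FALSE)
  if (any(!is.finite(charge_mean)) || any(charge_mean <= 0))
    stop("charges must be finite and strictly positive", call. = FALSE)
  if (any(charge_se < 0))
    stop("charge standard errors must be non-negative", call. = FALSE)
  if (any(n_repeats < 1L))
    stop("n_repeats must be >= 1", call. = FALSE)

  ord <- order(voltage)
  out <- data.frame(voltage = voltage[ord], charge_mean = charge_mean[ord],
                    charge_se = charge_se[ord], n_repeats = n_repeats[ord])

  # soft monotonicity check: charge should rise toward saturation
  dq <- diff(out$charge_mean)
  tol <- 3 * sqrt(out$charge_se[-n]^2 + out$charge_se[-1]^2)
  if (any(dq < -pmax(tol, .Machine$double.eps^0.5 * out$charge_mean[-n])))
    warning(sprintf(
      "collected charge decreases with voltage beyond noise in series %s @ %g Gy/s",
      chamber_id, dose_rate), call. = FALSE)

  structure(out, chamber_id = chamber_id, dose_rate = dose_rate,
            polarity = polarity,
            class = c("charge_voltage_series", "data.frame"))
}

#' @export
print.charge_voltage_series <- function(x, ...) {
  cat(sprintf("<charge_voltage_series> chamber %s, %g Gy/s, polarity %s, %d voltages\n",
              attr(x, "chamber_id"), attr(x, "dose_rate"),
              attr(x, "polarity"), nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Read charge-versus-voltage measurements from CSV
#'
#' Expects one row per individual reading with columns `chamber_id`,
#' `dose_rate_gy_s`, `voltage_v`, `charge_nc` and `polarity` (comma-separated,
#' header required, `.` decimal separator, units fixed at nC / V / Gy/s).
#' Repeat readings at the same voltage are aggregated to a mean, a standard
#' error of the mean and a repeat count.
#'
#' @param path Path to the CSV file.
#' @return A list of [charge_voltage_series()] objects, one per
#'   (chamber, dose rate, polarity) combination, ordered by dose rate.
#' @export
read_charge_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("charge CSV not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("chamber_id", "dose_rate_gy_s", "voltage_v", "charge_nc", "polarity")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("charge CSV %s lacks required columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L)
    stop(sprintf("charge CSV %s contains no data rows", path), call. = FALSE)
  bad <- which(!is.finite(df$voltage_v) | !is.finite(df$charge_nc))
  if (length(bad))
    stop(sprintf("charge CSV %s: non-numeric value at data line %d", path,
                 bad[1] + 1L), call. = FALSE)

  key <- interaction(df$chamber_id, df$dose_rate_gy_s, df$polarity, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    byv <- split(g$charge_nc, round(g$voltage_v, 1))
    v <- as.numeric(names(byv))
    m <- vapply(byv, mean, 0)
    n <- lengths(byv)
    se <- vapply(byv, function(q) if (length(q) > 1L) stats::sd(q) / sqrt(length(q)) else 0, 0)
    charge_voltage_series(g$chamber_id[1], g$dose_rate_gy_s[1],
                          voltage = v, charge_mean = m, charge_se = se,
                          n_repeats = n, polarity = g$polarity[1])
  })
  out <- unname(out)
  out[order(vapply(out, function(s) attr(s, "dose_rate"), 0))]
}

#' Write a list of charge-voltage series back to the measurement CSV dialect
#'
#' Inverse of [read_charge_csv()]: when a series carries the individual
#' repeat readings (as simulated series do, via `attr(, "repeat_charges")`)
#' one row per reading is written and the round trip preserves means and
#' standard errors; otherwise one row per voltage mean is written.
#'
#' @param series_list List of [charge_voltage_series()] objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_charge_csv <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s) {
    reps <- attr(s, "repeat_charges")
    if (is.null(reps)) {
      v <- s$voltage; q <- s$charge_mean
    } else {
      v <- rep(s$voltage, times = ncol(reps))
      q <- as.vector(reps)
    }
    data.frame(chamber_id = attr(s, "chamber_id"),
               dose_rate_gy_s = attr(s, "dose_rate"),
               voltage_v = v, charge_nc = q,
               polarity = attr(s, "polarity"))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
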