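#' Ionization chamber specification
#'
#' Calibration constants of a plane-parallel chamber used for dose
#' determination: the absorbed-dose-to-water calibration coefficient
#' \eqn{N_{D,w}} (Gy/nC, from a Co-60 beam), the electrode gap (mm) and the
#' reference bias voltage (V).
#'
#' @param name Chamber model name.
#' @param nd_w Calibration coefficient in Gy/nC (> 0).
#' @param electrode_gap Electrode spacing in mm (> 0).
#' @param reference_voltage Reference bias voltage in V.
#' @param serial Serial number (text), optional.
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(name, nd_w, electrode_gap, reference_voltage = 300,
                         serial = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(nd_w) || nd_w <= 0)
    .err("nd_w must be positive", "uhdr_domain_error")
  if (!is.finite(electrode_gap) || electrode_gap <= 0)
    .err("electrode_gap must be positive", "uhdr_domain_error")
  structure(list(name = name, nd_w = nd_w, electrode_gap = electrode_gap,
                 reference_voltage = reference_voltage, serial = serial),
            class = "chamber_spec")
}

#' Read a chamber specification from YAML or JSON
#'
#' Expects keys `name`, `nd_w_gy_per_nc`, `electrode_gap_mm`,
#' `reference_voltage_v` and optionally `serial`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [chamber_spec()].
#' @export
read_chamber_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("chamber config not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  req <- c("name", "nd_w_gy_per_nc", "electrode_gap_mm")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop(sprintf("chamber config %s lacks: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  chamber_spec(cfg$name, cfg$nd_w_gy_per_nc, cfg$electrode_gap_mm,
               cfg$reference_voltage_v %||% 300, cfg$serial %||% "")
}

#' A single corrected-charge measurement
#'
#' One electrometer reading with the ambient conditions needed for the
#' air-density correction. Charge sign is taken as magnitude; polarity is
#' retained as metadata.
#'
#' @param raw_charge Collected charge in nC (> 0, magnitude).
#' @param temperature Air temperature in deg C.
#' @param pressure Air pressure in kPa; a value outside (80, 110) kPa
#'   triggers a sanity warning.
#' @param voltage Bias voltage in V.
#' @param polarity `"+"` or `"-"`.
#' @param field_id Field label, e.g. `"5x6"`.
#' @return An object of class `chamber_reading`.
#' @export
chamber_reading <- function(raw_charge, temperature = 20, pressure = 101.325,
                            voltage = 300, polarity = "+", field_id = "") {
  if (!is.finite(raw_charge) || raw_charge <= 0)
    .err("raw_charge must be positive", "uhdr_domain_error")
  polarity <- match.arg(polarity, c("+", "-"))
  if (pressure <= 80 || pressure >= 110)
    warning(sprintf("pressure %.1f kPa outside the (80, 110) kPa sanity band",
                    pressure), call. = FALSE)
  structure(list(raw_charge = abs(raw_charge), temperature = temperature,
                 pressure = pressure, voltage = voltage, polarity = polarity,
                 field_id = field_id),
            class = "chamber_reading")
}

#' Temperature-pressure (air density) correction factor
#'
#' \deqn{k_{TP} = \frac{273.2 + T}{273.2 + T_{ref}} \cdot \frac{P_{ref}}{P}}
#' corrects the chamber reading to the air density of the calibration
#' reference conditions (TRS-398 convention: 20 deg C, 101.325 kPa; labs
#' calibrated at 22 deg C can override `t_ref`).
#'
#' @param temperature Measured air temperature in deg C (> -273.2).
#' @param pressure Measured air pressure in kPa (> 0).
#' @param t_ref,p_ref Reference conditions; defaults 20 deg C, 101.325 kPa.
#' @return Dimensionless correction factor.
#' @examples
#' k_tp(22, 101.325)   # warm air, less dense: reading corrected up
#' @export
k_tp <- function(temperature, pressure, t_ref = 20, p_ref = 101.325) {
  if (any(temperature <= -273.2))
    .err("temperature must exceed absolute zero", "uhdr_domain_error")
  if (any(pressure <= 0))
    .err("pressure must be positive", "uhdr_domain_error")
  ((273.2 + temperature) / (273.2 + t_ref)) * (p_ref / pressure)
}

#' Polarity correction factor
#'
#' \deqn{k_{pol} = \frac{|Q_+| + |Q_-|}{2\,|Q_{routine}|}} where the routine
#' polarity is the one used clinically.
#'
#' @param charge_plus,charge_minus Charges (nC) collected at positive and
#'   negative bias; signs are ignored.
#' @param routine Which polarity is used routinely, `"+"` (default) or `"-"`.
#' @return Dimensionless correction factor.
#' @export
k_pol <- function(charge_plus, charge_minus, routine = c("+", "-")) {
  routine <- match.arg(routine)
  qr <- if (routine == "+") charge_plus else charge_minus
  if (any(qr == 0))
    .err("routine-polarity charge must be nonzero", "uhdr_domain_error")
  (abs(charge_plus) + abs(charge_minus)) / (2 * abs(qr))
}

#' Absorbed dose to water from a chamber reading (TRS-398)
#'
#' \deqn{D_w = M \, k_{TP} \, k_{pol} \, k_s \, N_{D,w} \, k_Q}
#' where `M` is the raw charge, \eqn{k_s} the recombination correction (a
#' [ks_at()] / [ks_two_voltage()] result or a plain number), \eqn{N_{D,w}}
#' the Co-60 calibration coefficient and \eqn{k_Q} the beam quality
#' conversion factor, supplied by the caller (no internal beam-quality
#' table). \eqn{k_{pol}} defaults to 1.
#'
#' The relative standard uncertainty of the dose is the quadrature sum of
#' the relative uncertainties of `M`, \eqn{k_s} (taken from the `ks_result`
#' when one is supplied) and \eqn{k_Q}.
#'
#' @param reading A [chamber_reading()].
#' @param spec A [chamber_spec()].
#' @param ks A `ks_result` or a dimensionless number (> 0).
#' @param k_q Beam quality conversion factor (> 0).
#' @param k_pol Polarity correction, default 1.
#' @param u_rel_m Relative standard uncertainty of the charge reading
#'   (fraction), default 0.
#' @param u_rel_kq Relative standard uncertainty of `k_q` (fraction),
#'   default 0.
#' @param u_rel_ks Relative uncertainty of `ks`; defaults to the one carried
#'   by the `ks_result`, or 0 for a plain number.
#' @return An object of class `dose_result`: list with `dose` (Gy), `u_dose`
#'   (Gy) and the `corrections` applied.
#' @examples
#' sp <- chamber_spec("advanced_markus", nd_w = 1.521, electrode_gap = 1.0)
#' rd <- chamber_reading(5.030, field_id = "5x6")
#' dose_to_water(rd, sp, ks = 1.005, k_q = 1)
#' @export
dose_to_water <- function(reading, spec, ks, k_q, k_pol = 1,
                          u_rel_m = 0, u_rel_kq = 0, u_rel_ks = NULL) {
  stopifnot(inherits(reading, "chamber_reading"), inherits(spec, "chamber_spec"))
  if (inherits(ks, "ks_result")) {
    if (!is.null(ks$voltage) && is.finite(ks$voltage) &&
        abs(ks$voltage - reading$voltage) > 0.1)
      warning(sprintf("ks was evaluated at %g V but the reading is at %g V",
                      ks$voltage, reading$voltage), call. = FALSE)
    if (is.null(u_rel_ks)) u_rel_ks <- ks$u_ks / ks$ks
    ks_val <- ks$ks
  } else {
    ks_val <- ks
    if (is.null(u_rel_ks)) u_rel_ks <- 0
  }
  if (!is.finite(k_q) || k_q <= 0)
    .err("k_q must be positive", "uhdr_domain_error")
  if (ks_val <= 0 || k_pol <= 0)
    .err("correction factors must be positive", "uhdr_domain_error")
  ktp <- k_tp(reading$temperature, reading$pressure)
  corrections <- c(k_tp = ktp, k_pol = k_pol, k_s = ks_val, k_q = k_q)
  dose <- reading$raw_charge * ktp * k_pol * ks_val * spec$nd_w * k_q
  u_rel <- sqrt(u_rel_m^2 + u_rel_ks^2 + u_rel_kq^2)
  structure(list(dose = dose, u_dose = dose * u_rel,
                 corrections = corrections,
                 field_id = reading$field_id, chamber = spec$name),
            class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("<dose_result> %s%s: %.4f +/- %.4f Gy  [k_tp %.4f, k_pol %.4f, k_s %.4f, k_q %.4f]\n",
              x$chamber, if (nzchar(x$field_id)) paste0(" field ", x$field_id) else "",
              x$dose, x$u_dose, x$corrections["k_tp"], x$corrections["k_pol"],
              x$corrections["k_s"], x$corrections["k_q"]))
  invisible(x)
}

#' Electric field strength in the chamber gap
#'
#' Bias voltage divided by electrode spacing, in V/mm. Small-gap chambers
#' reach field strengths where charge multiplication becomes non-negligible
#' (e.g. 500 V/mm for a 0.6 mm gap at 300 V).
#'
#' @param voltage Bias voltage in V (>= 0).
#' @param gap Electrode spacing in mm (> 0).
#' @return Field strength in V/mm.
#' @export
electric_field_strength <- function(voltage, gap) {
  if (any(gap <= 0))
    .err("electrode gap must be positive", "uhdr_domain_error")
  voltage / gap
}

#' Mean and standard deviation of the mean of repeat doses
#'
#' @param doses Numeric vector of at least 2 repeat dose values (Gy).
#' @return A list with `mean` and `sdom` (sample SD / sqrt(n)).
#' @export
aggregate_repeats <- function(doses) {
  if (length(doses) < 2L)
    .err("at least 2 repeat values are required", "uhdr_input_error")
  list(mean = mean(doses), sdom = stats::sd(doses) / sqrt(length(doses)))
}
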