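#' Chamber-versus-calorimeter ratio for one field
#'
#' The ratio of the chamber-determined dose to the calorimeter reference
#' dose, the headline quantity of a dosimetric intercomparison. Two
#' uncertainty conventions are supported: `"chamber"` (default) propagates
#' only the chamber statistical uncertainty, matching the convention of
#' reporting the reproducibility on the ratio while the calorimeter's
#' systematic budget is quoted separately; `"quadrature"` combines both
#' relative uncertainties.
#'
#' @param chamber_dose,calorimeter_dose Doses in Gy (> 0).
#' @param u_chamber,u_calorimeter Standard uncertainties in Gy, default 0.
#' @param field_id Field label.
#' @param mode `"chamber"` or `"quadrature"`.
#' @return An object of class `field_comparison`: list with `field_id`,
#'   doses and uncertainties, `ratio` and `u_ratio`.
#' @export
field_ratio <- function(chamber_dose, calorimeter_dose,
                        u_chamber = 0, u_calorimeter = 0, field_id = "",
                        mode = c("chamber", "quadrature")) {
  mode <- match.arg(mode)
  if (chamber_dose <= 0 || calorimeter_dose <= 0)
    .err("doses must be positive", "uhdr_domain_error")
  ratio <- chamber_dose / calorimeter_dose
  rel_ch <- u_chamber / chamber_dose
  rel_cal <- u_calorimeter / calorimeter_dose
  u_rel <- if (mode == "chamber") rel_ch else sqrt(rel_ch^2 + rel_cal^2)
  structure(list(field_id = field_id,
                 chamber_dose = chamber_dose, u_chamber = u_chamber,
                 calorimeter_dose = calorimeter_dose,
                 u_calorimeter = u_calorimeter,
                 ratio = ratio, u_ratio = ratio * u_rel, mode = mode),
            class = "field_comparison")
}

#' @export
print.field_comparison <- function(x, ...) {
  cat(sprintf("<field_comparison> %s: %.3f / %.3f Gy = %.3f +/- %.3f\n",
              x$field_id, x$chamber_dose, x$calorimeter_dose,
              round_half_up(x$ratio, 3), x$u_ratio))
  invisible(x)
}

#' Average chamber/calorimeter ratio over a set of fields
#'
#' Unweighted mean of the per-field ratios. The reported uncertainty is the
#' larger of the SDOM of the ratios and the mean per-field ratio
#' uncertainty, so a handful of fields with consistent ratios still carries
#' the per-field measurement uncertainty.
#'
#' @param comparisons List of [field_ratio()] results (>= 1).
#' @return A list with `mean`, `u`, `n` and the vector of `ratios`.
#' @export
average_ratio <- function(comparisons) {
  if (!length(comparisons))
    .err("at least one field comparison is required", "uhdr_input_error")
  ratios <- vapply(comparisons, function(x) x$ratio, 0)
  us <- vapply(comparisons, function(x) x$u_ratio, 0)
  n <- length(ratios)
  sdom <- if (n > 1L) stats::sd(ratios) / sqrt(n) else 0
  list(mean = mean(ratios), u = max(sdom, mean(us)), n = n, ratios = ratios)
}

#' Mean reference dose and its SDOM
#'
#' @param doses Numeric vector of per-field doses (Gy), at least 2.
#' @return A list with `mean` and `sdom`.
#' @export
mean_reference_dose <- function(doses) {
  if (length(doses) < 2L)
    .err("at least 2 dose values are required", "uhdr_input_error")
  list(mean = mean(doses), sdom = stats::sd(doses) / sqrt(length(doses)))
}

#' Agreement score between a dose ratio and unity
#'
#' A z-style score
#' \deqn{z = \frac{|r - 1|}{\sqrt{u_r^2 + u_{sys}^2}}}
#' comparing the departure of the chamber/calorimeter ratio from unity with
#' the combined statistical and systematic uncertainty. With the standard
#' ionometric (~2.3 %) and calorimetric (~1.5 %) systematic budgets, even a
#' 3 % discrepancy yields z near 1, i.e. not statistically significant.
#'
#' @param ratio Dose ratio (dimensionless).
#' @param u_ratio Statistical uncertainty of the ratio (absolute).
#' @param u_systematic Systematic uncertainty as a fraction of the ratio
#'   scale (e.g. `0.02746` for 2.746 %).
#' @param threshold Significance threshold on z, default 1.5 (configuration,
#'   not doctrine).
#' @return A list with `z`, `significant` (logical) and the inputs.
#' @export
agreement_score <- function(ratio, u_ratio, u_systematic, threshold = 1.5) {
  if (u_ratio < 0 || u_systematic <= 0)
    .err("uncertainties must be positive", "uhdr_domain_error")
  z <- abs(ratio - 1) / sqrt(u_ratio^2 + u_systematic^2)
  list(z = z, significant = z >= threshold, threshold = threshold,
       ratio = ratio, u_combined = sqrt(u_ratio^2 + u_systematic^2))
}

#' Field-wise comparison table of chamber and calorimeter doses
#'
#' Inner-joins two dose tables on `field_id`, forms the per-field ratios
#' (rounded half-up to 3 decimals in the `ratio_printed` column, the
#' convention of printed comparison tables) and the average ratio.
#'
#' @param chamber_df Data frame with columns `field_id`, `dose_gy` and
#'   optionally `u_gy` (chamber doses).
#' @param calorimeter_df Same layout for the calorimeter reference doses.
#' @param mode Ratio-uncertainty mode, see [field_ratio()].
#' @param u_systematic Systematic fraction for [agreement_score()], default
#'   `sqrt(0.023^2 + 0.015^2)` (ionometric and calorimetric budgets).
#' @param threshold Significance threshold on z.
#' @return A list with `table` (per-field data frame), `average` (from
#'   [average_ratio()]) and `agreement` (from [agreement_score()]).
#' @export
compare_doses <- function(chamber_df, calorimeter_df,
                          mode = c("chamber", "quadrature"),
                          u_systematic = sqrt(0.023^2 + 0.015^2),
                          threshold = 1.5) {
  mode <- match.arg(mode)
  need <- function(df, nm) {
    if (!all(c("field_id", "dose_gy") %in% names(df)))
      .err(sprintf("%s table needs columns field_id and dose_gy", nm),
           "uhdr_input_error")
    if (!"u_gy" %in% names(df)) df$u_gy <- 0
    df
  }
  chamber_df <- need(chamber_df, "chamber")
  calorimeter_df <- need(calorimeter_df, "calorimeter")
  common <- intersect(chamber_df$field_id, calorimeter_df$field_id)
  dropped <- setdiff(union(chamber_df$field_id, calorimeter_df$field_id), common)
  if (length(dropped))
    warning(sprintf("fields without a match dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  if (!length(common))
    .err("no overlapping field_ids between the two dose tables",
         "uhdr_input_error")
  comps <- lapply(common, function(f) {
    ch <- chamber_df[chamber_df$field_id == f, ][1, ]
    ca <- calorimeter_df[calorimeter_df$field_id == f, ][1, ]
    field_ratio(ch$dose_gy, ca$dose_gy, ch$u_gy, ca$u_gy, field_id = f,
                mode = mode)
  })
  tbl <- data.frame(
    field_id = common,
    chamber_dose_gy = vapply(comps, function(x) x$chamber_dose, 0),
    calorimeter_dose_gy = vapply(comps, function(x) x$calorimeter_dose, 0),
    ratio = vapply(comps, function(x) x$ratio, 0),
    u_ratio = vapply(comps, function(x) x$u_ratio, 0))
  tbl$ratio_printed <- round_half_up(tbl$ratio, 3)
  avg <- average_ratio(comps)
  agr <- agreement_score(avg$mean, avg$u, u_systematic, threshold)
  list(table = tbl, average = avg, agreement = agr)
}
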