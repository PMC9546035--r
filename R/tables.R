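#' Reference campaign tables shipped with the package
#'
#' Reference tables of the UHDR proton intercomparison campaign, shipped as
#' CSV under `inst/extdata` and used as inputs by the comparison stage and
#' as anchors by the test-suite:
#' \describe{
#'   \item{`dose_rates`}{nozzle current (nA) vs voxel-based mean dose rate
#'     (Gy/s) with its SD, for the 5 x 12 cm^2 recombination field.}
#'   \item{`calorimeter_doses`}{per-field provisional dose to water from the
#'     graphite calorimeter (Gy) with the expanded (k = 1) uncertainty.}
#'   \item{`chamber_doses`}{per-field chamber dose to water, SDOM, and the
#'     printed chamber/calorimeter ratio, for both chambers.}
#'   \item{`qp_extrapolation`}{saturation charges from the linear and the
#'     curve fit for each chamber, with the printed percent difference.}
#' }
#'
#' @param name One of `"dose_rates"`, `"calorimeter_doses"`,
#'   `"chamber_doses"`, `"qp_extrapolation"`.
#' @return A data frame.
#' @examples
#' uhdr_table("calorimeter_doses")
#' @export
uhdr_table <- function(name = c("dose_rates", "calorimeter_doses",
                                "chamber_doses", "qp_extrapolation")) {
  name <- match.arg(name)
  file <- c(dose_rates = "table1_dose_rates.csv",
            calorimeter_doses = "table2_calorimeter_doses.csv",
            chamber_doses = "table3_chamber_doses.csv",
            qp_extrapolation = "table4_qp_extrapolation.csv")[[name]]
  path <- system.file("extdata", file, package = "uhdrdosim", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
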