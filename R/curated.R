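#' Curated QM-derived study tables for the lead derivatives
#'
#' Small plain-text tables bundled with the package for the three lead
#' caffeic-acid derivatives (dCAF-2, dCAF-16, dCAF-82) reacting with the
#' hydroperoxyl radical, as produced by the electronic-structure stage of
#' the workflow (which this package consumes, not runs):
#'
#' \describe{
#'   \item{`pka`}{macroscopic pKa ladders (columns `compound`, `pka1`..).}
#'   \item{`channel_rates`}{per-channel apparent rate constants
#'     (M^-1 s^-1) by compound, solvent, protonation state and donor site.}
#'   \item{`thermochemistry`}{reaction free energies and activation
#'     barriers (kcal/mol) for every hydrogen-transfer,
#'     radical-adduct-formation and electron-transfer channel; `na` marks
#'     unavailable barriers, `barrierless` marks diffusion-controlled
#'     channels.}
#'   \item{`zone_energies`}{reaction-force zone components of the main
#'     channel (kcal/mol).}
#'   \item{`reference_rates`}{literature hydroperoxyl scavenging rate
#'     constants of the parent acid and reference antioxidants.}
#' }
#'
#' @param which one of `"pka"`, `"channel_rates"`, `"thermochemistry"`,
#'   `"zone_energies"`, `"reference_rates"`.
#' @return a data.frame (for `"pka"` use [readPkaTable()] to get
#'   [AcidBaseSystem-class] objects).
#' @examples
#' curatedDcafData("zone_energies")
#' @export
curatedDcafData <- function(which = c("pka", "channel_rates", "thermochemistry",
                                      "zone_energies", "reference_rates")) {
  which <- match.arg(which)
  file <- c(pka = "dcaf_pka.csv", channel_rates = "dcaf_channel_rates.csv",
            thermochemistry = "dcaf_thermochemistry.csv",
            zone_energies = "dcaf_zone_energies.csv",
            reference_rates = "reference_rate_constants.csv")[[which]]
  path <- system.file("extdata", file, package = "AntioxDesign",
                      mustWork = TRUE)
  if (which == "thermochemistry") return(readChannelTable(path))
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("na", "NA", ""))
}

#' Acid-base systems of the lead derivatives
#'
#' Convenience wrapper turning the curated pKa table into
#' [AcidBaseSystem-class] objects.
#'
#' @return named list of [AcidBaseSystem-class].
#' @examples
#' speciationFractions(dcafAcidBaseSystems()[["dCAF-16"]], 7.4)
#' @export
dcafAcidBaseSystems <- function() {
  readPkaTable(system.file("extdata", "dcaf_pka.csv",
                           package = "AntioxDesign", mustWork = TRUE))
}
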