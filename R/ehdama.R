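#' Build an electron/hydrogen donating-ability map
#'
#' Assembles candidate and reference species into a BDE-vs-IE map.  The
#' minimum bond dissociation energy over each species' donor sites is used
#' as its H-donation coordinate (every site that can act as an H donor
#' counts).  Exactly one `reference_oxidant_pair` point must be present; its
#' BDE sets the H-donation reference line (the O-H bond strength of the
#' oxidant's conjugate) and its IE the electron-transfer reference line.
#'
#' @param bde data.frame with columns `species_id`, `site`, `BDE` (kcal/mol;
#'   one row per donor site) or columns `species_id`, `BDE` (already
#'   site-minimised).
#' @param ie data.frame with columns `species_id`, `IE` (kcal/mol) and
#'   `role` (one of `candidate`, `reference_antioxidant`,
#'   `reference_oxidant_pair`).
#' @return An [EHDAMAMap-class] object.
#' @examples
#' bde <- data.frame(species_id = c("x", "x", "hooh"), site = c("O1", "O2", "O"),
#'                   BDE = c(80, 84, 87.8))
#' ie <- data.frame(species_id = c("x", "hooh"), IE = c(160, 105),
#'                  role = c("candidate", "reference_oxidant_pair"))
#' buildEHDAMA(bde, ie)
#' @export
buildEHDAMA <- function(bde, ie) {
  if (!all(c("species_id", "BDE") %in% names(bde)))
    stop("bde needs columns species_id and BDE")
  if (!all(c("species_id", "IE", "role") %in% names(ie)))
    stop("ie needs columns species_id, IE and role")
  minBDE <- stats::aggregate(BDE ~ species_id, bde, min)
  pts <- merge(minBDE, ie, by = "species_id", all = TRUE)
  if (anyNA(pts$BDE) || anyNA(pts$IE))
    stop("every species needs both a BDE and an IE value: ",
         paste(pts$species_id[is.na(pts$BDE) | is.na(pts$IE)], collapse = ", "))
  refIdx <- which(pts$role == "reference_oxidant_pair")
  if (length(refIdx) != 1L)
    stop("exactly one reference_oxidant_pair point is required, found ",
         length(refIdx))
  new("EHDAMAMap", points = pts[, c("species_id", "BDE", "IE", "role")],
      bdeThreshold = pts$BDE[refIdx], ieThreshold = pts$IE[refIdx])
}

#' Classify a species on the donating-ability map
#'
#' A species is a good H donor when its minimum BDE lies below the map's
#' H-donation reference line (its X-H bond is weaker than the one the
#' oxidant would form, so formal hydrogen transfer is exergonic at the level
#' of the inputs); electron transfer is viable when its IE lies below the
#' electron-transfer line.  `beats` lists the comparator species with
#' strictly higher BDE, i.e. the ones it out-performs as an H donor.
#'
#' @param map an [EHDAMAMap-class].
#' @param speciesId the species to classify (must be on the map).
#' @param comparators character vector of comparator species ids (e.g. the
#'   parent compound and reference antioxidants); defaults to every
#'   `reference_antioxidant` on the map.
#' @return list with `good_H_donor`, `SET_viable`, `on_line` (tie flags) and
#'   `beats`.
#' @export
classifySpecies <- function(map, speciesId, comparators = NULL) {
  stopifnot(is(map, "EHDAMAMap"))
  pts <- map@points
  i <- match(speciesId, pts$species_id)
  if (is.na(i)) stop("species not on the map: ", speciesId)
  if (is.null(comparators))
    comparators <- pts$species_id[pts$role == "reference_antioxidant"]
  comparators <- setdiff(comparators, speciesId)
  missing <- setdiff(comparators, pts$species_id)
  if (length(missing))
    stop("comparator(s) not on the map: ", paste(missing, collapse = ", "))
  cmpBDE <- pts$BDE[match(comparators, pts$species_id)]
  list(good_H_donor = pts$BDE[i] < map@bdeThreshold,
       SET_viable = pts$IE[i] < map@ieThreshold,
       on_line = c(BDE = pts$BDE[i] == map@bdeThreshold,
                   IE = pts$IE[i] == map@ieThreshold),
       beats = comparators[cmpBDE > pts$BDE[i]])
}
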