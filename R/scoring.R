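# Properties scored against the reference cohort.
.admeProps <- c("HBD", "HBA", "MW", "logP", "MR", "AtX", "RB", "PSA")
.toxProps  <- c("LD50", "ames")
.saProp    <- "SA"

#' Desirability windows for the ADME properties
#'
#' The per-property compliance windows used by the selection score: the
#' intersection of the applicable Lipinski/Ghose/Veber bounds, in the units
#' of each descriptor.  A value inside its window contributes a desirability
#' of 1; outside, desirability decays with the standardized distance to the
#' nearest bound.  Exposed so that unit changes (or a bespoke scheme) can be
#' applied consistently.
#'
#' @return named list of `c(lower, upper)` windows.
#' @examples propertyWindows()$MW
#' @export
propertyWindows <- function() {
  list(HBD = c(0, 5), HBA = c(0, 10), MW = c(160, 480), logP = c(-0.4, 5),
       MR = c(40, 130), AtX = c(20, 70), RB = c(0, 10), PSA = c(0, 140))
}

#' Weights of the three selection-score terms
#'
#' @param adme,tox,sa non-negative weights of the drug-likeness, toxicity and
#'   synthetic-accessibility terms.
#' @return named numeric vector.
#' @examples scoreWeights(sa = 0)
#' @export
scoreWeights <- function(adme = 1, tox = 1, sa = 1) {
  w <- c(adme = adme, tox = tox, sa = sa)
  if (any(w < 0)) stop("weights must be non-negative")
  w
}

#' Build per-property aggregates over a reference compound set
#'
#' Computes the arithmetic mean and sample standard deviation of every scored
#' property over the reference cohort.  The cohort itself is retained on the
#' returned object so that score normalisation can be recomputed for any
#' weight choice.
#'
#' @param records data.frame of descriptor records (schema of
#'   [computeDescriptors()], with the external `LD50`, `ames`, `SA` columns
#'   filled in).
#' @param properties which columns to aggregate; defaults to the eight ADME
#'   descriptors plus `LD50`, `ames` and `SA` where present.
#' @return A [ReferenceAggregates-class] object.
#' @export
buildReferenceAggregates <- function(records,
                                     properties = intersect(c(.admeProps, .toxProps, .saProp),
                                                            names(records))) {
  if (nrow(records) < 2L)
    stop("insufficient data: need at least 2 reference records")
  ids <- if ("id" %in% names(records)) records$id else as.character(seq_len(nrow(records)))
  for (p in properties) {
    if (!p %in% names(records))
      stop("incomplete record: property ", p, " absent from reference table")
    bad <- which(is.na(records[[p]]))
    if (length(bad))
      stop(sprintf("incomplete record: compound %s lacks property %s",
                   ids[bad[1]], p))
  }
  stats <- data.frame(property = properties,
                      mean = vapply(properties, function(p) mean(records[[p]]), 0),
                      sd   = vapply(properties, function(p) stats::sd(records[[p]]), 0),
                      stringsAsFactors = FALSE)
  rownames(stats) <- NULL
  new("ReferenceAggregates", stats = stats, n = nrow(records),
      records = as.data.frame(records))
}

.aggLookup <- function(agg, prop, what = c("mean", "sd")) {
  what <- match.arg(what)
  i <- match(prop, agg@stats$property)
  if (is.na(i)) stop("aggregates do not cover property ", prop)
  agg@stats[[what]][i]
}

# Desirability of one ADME property vector: 1 inside the compliance window,
# 1/(1 + distance-to-window in reference-sd units) outside.
.windowDesirability <- function(v, window, sd) {
  if (!is.finite(sd) || sd <= 0) sd <- 1
  dist <- pmax(0, window[1] - v, v - window[2]) / sd
  1 / (1 + dist)
}

# Increasing logistic desirability centred on the reference mean.
.logisticDesirability <- function(v, mean, sd) {
  if (!is.finite(sd) || sd <= 0) sd <- 1
  1 / (1 + exp(-(v - mean) / sd))
}

# Raw (unnormalised) score terms for a descriptor frame.
.rawScoreTerms <- function(d, agg, weights, windows) {
  n <- nrow(d)
  admeD <- matrix(NA_real_, n, length(.admeProps),
                  dimnames = list(NULL, .admeProps))
  for (p in .admeProps) {
    if (!p %in% names(d) || anyNA(d[[p]]))
      stop("incomplete record: property ", p, " missing for scoring")
    admeD[, p] <- .windowDesirability(d[[p]], windows[[p]],
                                      .aggLookup(agg, p, "sd"))
  }
  S_ADME <- rowMeans(admeD)
  S_T <- rep(NA_real_, n)
  if (weights[["tox"]] > 0) {
    if (!"LD50" %in% names(d) || anyNA(d$LD50))
      stop("incomplete record: LD50 required when the toxicity term has nonzero weight")
    dT <- .logisticDesirability(d$LD50, .aggLookup(agg, "LD50", "mean"),
                                .aggLookup(agg, "LD50", "sd"))
    if ("ames" %in% names(d) && !anyNA(d$ames))
      dT <- (dT + (1 - d$ames)) / 2
    S_T <- dT
  } else S_T <- rep(0, n)
  if (weights[["sa"]] > 0) {
    if (!"SA" %in% names(d) || anyNA(d$SA))
      stop("incomplete record: SA required when the synthesizability term has nonzero weight")
    S_SA <- .logisticDesirability(d$SA, .aggLookup(agg, "SA", "mean"),
                                  .aggLookup(agg, "SA", "sd"))
  } else S_SA <- rep(0, n)
  raw <- weights[["adme"]] * S_ADME + weights[["tox"]] * S_T + weights[["sa"]] * S_SA
  data.frame(S_ADME = S_ADME, S_T = S_T, S_SA = S_SA, raw = raw)
}

#' Selection score of candidate compounds
#'
#' Scores descriptor records against a reference cohort.  Each property maps
#' to a desirability in `[0, 1]`: rule-compliant ADME values score 1 and
#' decay with standardized distance outside their compliance window, while
#' LD50 (higher = less toxic) and synthetic accessibility (higher = easier)
#' use increasing logistic desirabilities and Ames mutagenicity enters as
#' `1 - probability`.  The selection score is the weighted sum of the
#' drug-likeness, toxicity and synthesizability terms, rescaled so that the
#' reference cohort's mean score is exactly 1: candidates above 1 are more
#' desirable than the average reference compound.
#'
#' @param d data.frame of descriptor records to score.
#' @param agg [ReferenceAggregates-class] built from the reference cohort.
#' @param weights see [scoreWeights()].
#' @param windows see [propertyWindows()].
#' @return data.frame with columns `id`, `S_ADME`, `S_T`, `S_SA`, `S_S`.
#' @export
selectionScore <- function(d, agg, weights = scoreWeights(),
                           windows = propertyWindows()) {
  stopifnot(is(agg, "ReferenceAggregates"))
  terms <- .rawScoreTerms(d, agg, weights, windows)
  refRaw <- .rawScoreTerms(agg@records, agg, weights, windows)$raw
  norm <- mean(refRaw)
  if (!is.finite(norm) || norm <= 0)
    stop("degenerate reference set: mean raw score is not positive")
  data.frame(id = if ("id" %in% names(d)) d$id else as.character(seq_len(nrow(d))),
             S_ADME = terms$S_ADME, S_T = terms$S_T, S_SA = terms$S_SA,
             S_S = terms$raw / norm, stringsAsFactors = FALSE)
}

#' Elimination score: outlier deviation from the reference set
#'
#' For every scored property the standardized deviation
#' `z = (value - mean) / sd` from the reference aggregates is computed; the
#' elimination score is the number of properties with `|z|` above
#' `zThreshold`.  Deviations that are desirable on their own terms -- LD50 or
#' synthetic accessibility above the reference mean -- are still flagged but
#' marked benign.  Properties with zero reference spread are compared by
#' equality.
#'
#' @param d data.frame of descriptor records.
#' @param agg [ReferenceAggregates-class].
#' @param zThreshold flag threshold in sd units (default 2).
#' @return list with `scores` (data.frame `id`, `S_E`) and `flags`
#'   (data.frame `id`, `property`, `z`, `direction`, `benign`).
#' @export
eliminationScore <- function(d, agg, zThreshold = 2) {
  stopifnot(is(agg, "ReferenceAggregates"))
  ids <- if ("id" %in% names(d)) d$id else as.character(seq_len(nrow(d)))
  props <- intersect(agg@stats$property, names(d))
  flags <- list()
  SE <- integer(nrow(d))
  for (p in props) {
    m <- .aggLookup(agg, p, "mean"); s <- .aggLookup(agg, p, "sd")
    v <- d[[p]]
    z <- if (s > 0) (v - m) / s else ifelse(v == m, 0, Inf * sign(v - m))
    hit <- which(is.finite(v) & abs(z) > zThreshold)
    if (length(hit)) {
      SE[hit] <- SE[hit] + 1L
      flags[[p]] <- data.frame(id = ids[hit], property = p, z = z[hit],
                               direction = ifelse(z[hit] > 0, "above", "below"),
                               benign = p %in% c("LD50", "SA") & z[hit] > 0,
                               stringsAsFactors = FALSE)
    }
  }
  flags <- if (length(flags)) do.call(rbind, c(flags, make.row.names = FALSE)) else
    data.frame(id = character(), property = character(), z = numeric(),
               direction = character(), benign = logical())
  list(scores = data.frame(id = ids, S_E = SE, stringsAsFactors = FALSE),
       flags = flags)
}

#' Select candidates that beat both thresholds
#'
#' Keeps the records whose selection score is strictly greater than both the
#' reference-set score and the parent compound's score, sorted by decreasing
#' score (ties broken by id, stable).
#'
#' @param scores data.frame with columns `id` and `S_S` (as from
#'   [selectionScore()]).
#' @param thresholds numeric with elements `reference` and `parent`.
#' @return the selected subset of `scores`, ranked.
#' @examples
#' selectCandidates(data.frame(id = c("a", "b", "c"),
#'                             S_S = c(1.02, 1.05, 1.03)),
#'                  c(reference = 1.0, parent = 1.03))
#' @export
selectCandidates <- function(scores, thresholds = c(reference = 1.0, parent = 1.0)) {
  cut <- max(thresholds)
  sel <- scores[scores$S_S > cut, , drop = FALSE]
  sel <- sel[order(-sel$S_S, sel$id), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}
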