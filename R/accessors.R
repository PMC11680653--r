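# Accessor generics and methods.  Slot access from user code should go
# through these, never through @.

#' @rdname ScaffoldSpec-class
#' @param x object to access
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))
#' @rdname ScaffoldSpec-class
#' @export
setMethod("siteLabels", "ScaffoldSpec", function(x) x@siteLabels)

#' @rdname ScaffoldSpec-class
#' @export
setGeneric("substituentLibrary", function(x) standardGeneric("substituentLibrary"))
#' @rdname ScaffoldSpec-class
#' @export
setMethod("substituentLibrary", "ScaffoldSpec", function(x) x@fragments)

#' @rdname ReferenceAggregates-class
#' @param x object to access
#' @export
setGeneric("aggregateStats", function(x) standardGeneric("aggregateStats"))
#' @rdname ReferenceAggregates-class
#' @export
setMethod("aggregateStats", "ReferenceAggregates", function(x) x@stats)

#' @rdname ReferenceAggregates-class
#' @export
setGeneric("referenceRecords", function(x) standardGeneric("referenceRecords"))
#' @rdname ReferenceAggregates-class
#' @export
setMethod("referenceRecords", "ReferenceAggregates", function(x) x@records)

#' @rdname AcidBaseSystem-class
#' @param x object to access
#' @export
setGeneric("compoundId", function(x) standardGeneric("compoundId"))
#' @rdname AcidBaseSystem-class
#' @export
setMethod("compoundId", "AcidBaseSystem", function(x) x@compoundId)

#' @rdname AcidBaseSystem-class
#' @export
setGeneric("pkaValues", function(x) standardGeneric("pkaValues"))
#' @rdname AcidBaseSystem-class
#' @export
setMethod("pkaValues", "AcidBaseSystem", function(x) x@pka)

#' @rdname AcidBaseSystem-class
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))
#' @rdname AcidBaseSystem-class
#' @export
setMethod("speciesLabels", "AcidBaseSystem", function(x) x@speciesLabels)

#' @rdname IRCProfile-class
#' @param x object to access
#' @export
setGeneric("ircCoordinate", function(x) standardGeneric("ircCoordinate"))
#' @rdname IRCProfile-class
#' @export
setMethod("ircCoordinate", "IRCProfile", function(x) x@xi)

#' @rdname IRCProfile-class
#' @export
setGeneric("ircEnergy", function(x) standardGeneric("ircEnergy"))
#' @rdname IRCProfile-class
#' @export
setMethod("ircEnergy", "IRCProfile", function(x) x@energy)

#' @rdname ForceAnalysis-class
#' @param x object to access
#' @export
setGeneric("reactionForce", function(x) standardGeneric("reactionForce"))
#' @rdname ForceAnalysis-class
#' @export
setMethod("reactionForce", "ForceAnalysis", function(x) x@force)

#' @rdname ForceAnalysis-class
#' @export
setGeneric("criticalCoords", function(x) standardGeneric("criticalCoords"))
#' @rdname ForceAnalysis-class
#' @export
setMethod("criticalCoords", "ForceAnalysis", function(x)
  c(alpha = x@alpha, beta = x@beta, gamma = x@gamma))

#' @rdname ForceAnalysis-class
#' @export
setGeneric("zoneEnergies", function(x) standardGeneric("zoneEnergies"))
#' @rdname ForceAnalysis-class
#' @export
setMethod("zoneEnergies", "ForceAnalysis", function(x) x@zones)

#' @rdname ForceAnalysis-class
#' @export
setGeneric("zoneWork", function(x) standardGeneric("zoneWork"))
#' @rdname ForceAnalysis-class
#' @export
setMethod("zoneWork", "ForceAnalysis", function(x) x@work)

#' @rdname RateReport-class
#' @param x object to access
#' @export
setGeneric("channelRates", function(x) standardGeneric("channelRates"))
#' @rdname RateReport-class
#' @export
setMethod("channelRates", "RateReport", function(x) x@channels)

#' @rdname RateReport-class
#' @export
setGeneric("excludedChannels", function(x) standardGeneric("excludedChannels"))
#' @rdname RateReport-class
#' @export
setMethod("excludedChannels", "RateReport", function(x) x@excluded)

#' @rdname RateReport-class
#' @export
setGeneric("speciesTotals", function(x) standardGeneric("speciesTotals"))
#' @rdname RateReport-class
#' @export
setMethod("speciesTotals", "RateReport", function(x) x@totals)

#' @rdname RateReport-class
#' @export
setGeneric("globalRates", function(x) standardGeneric("globalRates"))
#' @rdname RateReport-class
#' @export
setMethod("globalRates", "RateReport", function(x) x@global)

#' @rdname EHDAMAMap-class
#' @param x object to access
#' @export
setGeneric("mapPoints", function(x) standardGeneric("mapPoints"))
#' @rdname EHDAMAMap-class
#' @export
setMethod("mapPoints", "EHDAMAMap", function(x) x@points)

#' @rdname EHDAMAMap-class
#' @export
setGeneric("mapThresholds", function(x) standardGeneric("mapThresholds"))
#' @rdname EHDAMAMap-class
#' @export
setMethod("mapThresholds", "EHDAMAMap", function(x)
  c(BDE = x@bdeThreshold, IE = x@ieThreshold))
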