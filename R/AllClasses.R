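#' @import methods
NULL

# ---------------------------------------------------------------------------
# ScaffoldSpec

#' ScaffoldSpec: a substitutable molecular scaffold
#'
#' Holds a core structure written as a SMILES template in which substitution
#' sites appear as `{R1}`, `{R2}`, ... tokens, together with the ordered site
#' labels and a substituent library.  Each library fragment is a SMILES string
#' with exactly one attachment point marked by the dummy atom `[*]`; hydrogen
#' is always implicitly available at every site and is not part of the
#' library.
#'
#' @slot core character(1), SMILES template containing one `({Rk})` token per
#'   site label.
#' @slot siteLabels character, ordered unique site labels (R1..Rn).
#' @slot fragments data.frame with columns `name` and `smiles` (one `[*]`
#'   attachment point each).
#' @seealso [scaffoldSpec()], [caffeicAcidScaffold()], [enumerateDerivatives()]
#' @exportClass ScaffoldSpec
setClass("ScaffoldSpec",
         representation(core = "character",
                        siteLabels = "character",
                        fragments = "data.frame"))

setValidity("ScaffoldSpec", function(object) {
  msg <- character()
  if (length(object@core) != 1L || !nzchar(object@core))
    msg <- c(msg, "core must be a single non-empty SMILES template")
  if (length(object@siteLabels) == 0L)
    msg <- c(msg, "siteLabels must be non-empty")
  if (anyDuplicated(object@siteLabels))
    msg <- c(msg, "siteLabels must be unique")
  for (lab in object@siteLabels)
    if (!grepl(paste0("{", lab, "}"), object@core, fixed = TRUE))
      msg <- c(msg, sprintf("core template lacks a {%s} token", lab))
  if (nrow(object@fragments)) {
    if (!all(c("name", "smiles") %in% names(object@fragments)))
      msg <- c(msg, "fragments needs columns 'name' and 'smiles'")
    else {
      napts <- vapply(object@fragments$smiles,
                      function(s) lengths(regmatches(s, gregexpr("[*]", s, fixed = TRUE))),
                      integer(1))
      bad <- object@fragments$name[napts != 1L]
      if (length(bad))
        msg <- c(msg, sprintf("fragment(s) without exactly one [*] attachment point: %s",
                              paste(bad, collapse = ", ")))
      if (anyDuplicated(object@fragments$name))
        msg <- c(msg, "fragment names must be unique")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ScaffoldSpec-class display a short summary
#' @param object a `ScaffoldSpec`
#' @export
setMethod("show", "ScaffoldSpec", function(object) {
  cat("ScaffoldSpec\n")
  cat("  core     :", object@core, "\n")
  cat("  sites    :", paste(object@siteLabels, collapse = ", "), "\n")
  cat("  library  :", if (nrow(object@fragments))
    paste(object@fragments$name, collapse = ", ") else "(empty)", "\n")
})

# ---------------------------------------------------------------------------
# ReferenceAggregates

#' ReferenceAggregates: per-property statistics of a reference compound set
#'
#' Arithmetic mean and sample standard deviation of every scored property over
#' a reference cohort, plus the cohort itself (kept so that score
#' normalisation can be recomputed for any choice of weights).
#'
#' @slot stats data.frame with columns `property`, `mean`, `sd`.
#' @slot n integer(1), number of reference compounds (>= 2).
#' @slot records data.frame, the reference descriptor table itself.
#' @seealso [buildReferenceAggregates()], [selectionScore()]
#' @exportClass ReferenceAggregates
setClass("ReferenceAggregates",
         representation(stats = "data.frame", n = "integer",
                        records = "data.frame"))

setValidity("ReferenceAggregates", function(object) {
  msg <- character()
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (!all(c("property", "mean", "sd") %in% names(object@stats)))
    msg <- c(msg, "stats needs columns property, mean, sd")
  else if (any(object@stats$sd < 0)) msg <- c(msg, "sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn ReferenceAggregates-class display a short summary
#' @param object a `ReferenceAggregates`
#' @export
setMethod("show", "ReferenceAggregates", function(object) {
  cat(sprintf("ReferenceAggregates over %d compounds\n", object@n))
  print(object@stats, row.names = FALSE, digits = 4)
})

# ---------------------------------------------------------------------------
# AcidBaseSystem

#' AcidBaseSystem: macroscopic pKa ladder of one compound
#'
#' An ordered list of macroscopic acid dissociation constants for successive
#' deprotonations of one compound.  A ladder of n pKa values defines n + 1
#' protonation states, labelled by net deprotonation count (neutral,
#' mono-anion, di-anion, ...).
#'
#' @slot compoundId character(1).
#' @slot pka numeric, strictly increasing.
#' @slot speciesLabels character, length `length(pka) + 1`.
#' @slot uncertainty numeric(1), stated pKa uncertainty (pKa units).
#' @seealso [acidBaseSystem()], [speciationFractions()], [distributionProfile()]
#' @exportClass AcidBaseSystem
setClass("AcidBaseSystem",
         representation(compoundId = "character", pka = "numeric",
                        speciesLabels = "character", uncertainty = "numeric"))

setValidity("AcidBaseSystem", function(object) {
  msg <- character()
  if (length(object@pka) < 1L) msg <- c(msg, "at least one pKa required")
  if (any(diff(object@pka) <= 0))
    msg <- c(msg, "pKa values must be strictly increasing")
  if (length(object@speciesLabels) != length(object@pka) + 1L)
    msg <- c(msg, "need one species label per protonation state (n pKa + 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn AcidBaseSystem-class display the ladder
#' @param object an `AcidBaseSystem`
#' @export
setMethod("show", "AcidBaseSystem", function(object) {
  cat(sprintf("AcidBaseSystem '%s': pKa = %s (+/- %.1f)\n", object@compoundId,
              paste(format(object@pka), collapse = ", "), object@uncertainty))
  cat("  species:", paste(object@speciesLabels, collapse = " -> "), "\n")
})

# ---------------------------------------------------------------------------
# IRCProfile

#' IRCProfile: potential energy along an intrinsic reaction coordinate
#'
#' A sampled potential energy profile along the reaction coordinate, which
#' increases from reactants to products; energies are stored in kcal/mol
#' (hartree input is converted at construction).  Validity demands at least
#' 7 points and a strictly increasing coordinate.  The critical-point
#' machinery additionally requires a single interior barrier (see
#' [criticalPoints()], which raises a no-transition-state error otherwise);
#' [singleBarrier()] tests that requirement.
#'
#' @slot xi numeric, strictly increasing reaction coordinate.
#' @slot energy numeric, potential energy in kcal/mol.
#' @seealso [ircProfile()], [forceProfile()], [analyzeReactionForce()]
#' @exportClass IRCProfile
setClass("IRCProfile", representation(xi = "numeric", energy = "numeric"))

setValidity("IRCProfile", function(object) {
  msg <- character()
  n <- length(object@xi)
  if (n < 7L) msg <- c(msg, "profile needs at least 7 points")
  if (length(object@energy) != n)
    msg <- c(msg, "xi and energy lengths differ")
  if (n >= 2L && any(diff(object@xi) <= 0))
    msg <- c(msg, "xi must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn IRCProfile-class display a short summary
#' @param object an `IRCProfile`
#' @export
setMethod("show", "IRCProfile", function(object) {
  cat(sprintf("IRCProfile: %d points, xi in [%.3g, %.3g], barrier %.3f kcal/mol\n",
              length(object@xi), min(object@xi), max(object@xi),
              max(object@energy) - object@energy[1]))
})

# ---------------------------------------------------------------------------
# ForceAnalysis

#' ForceAnalysis: reaction-force decomposition of an IRC profile
#'
#' Result container of [analyzeReactionForce()]: the reaction force on the
#' sampling grid, the refined alpha/beta/gamma critical points, the zone
#' energy decomposition of the forward and reverse activation energies, and
#' the reaction-force work integrals W1..W4.
#'
#' @slot profile the analysed [IRCProfile-class].
#' @slot force numeric, reaction force -dV/dxi on the profile grid (kcal/mol
#'   per coordinate unit).
#' @slot alpha,beta,gamma numeric(1), critical-point coordinates
#'   (alpha < beta < gamma; beta is the transition state).
#' @slot zones named numeric: `prep_forward` (reactants -> alpha),
#'   `transition_forward` (alpha -> beta), `prep_reverse` (products -> gamma),
#'   `transition_reverse` (gamma -> beta), `act_forward`, `act_reverse`, all
#'   kcal/mol.
#' @slot work named numeric `W1`..`W4`, area under the force curve per zone.
#' @slot method character(1), differentiation method used.
#' @exportClass ForceAnalysis
setClass("ForceAnalysis",
         representation(profile = "IRCProfile", force = "numeric",
                        alpha = "numeric", beta = "numeric", gamma = "numeric",
                        zones = "numeric", work = "numeric",
                        method = "character"))

setValidity("ForceAnalysis", function(object) {
  if (!(object@alpha < object@beta && object@beta < object@gamma))
    "critical points must satisfy alpha < beta < gamma" else TRUE
})

#' @describeIn ForceAnalysis-class display the decomposition
#' @param object a `ForceAnalysis`
#' @export
setMethod("show", "ForceAnalysis", function(object) {
  cat("ForceAnalysis (", object@method, ")\n", sep = "")
  cat(sprintf("  alpha = %.4f  beta = %.4f  gamma = %.4f\n",
              object@alpha, object@beta, object@gamma))
  z <- object@zones
  cat(sprintf("  dE_act forward  %.3f = %.3f (reactants->alpha) + %.3f (alpha->beta)\n",
              z["act_forward"], z["prep_forward"], z["transition_forward"]))
  cat(sprintf("  dE_act reverse  %.3f = %.3f (products->gamma) + %.3f (gamma->beta)\n",
              z["act_reverse"], z["prep_reverse"], z["transition_reverse"]))
})

# ---------------------------------------------------------------------------
# EHDAMAMap

#' EHDAMAMap: electron/hydrogen donating-ability map
#'
#' A set of (BDE, IE) points for candidate and reference species together
#' with the classification thresholds taken from the single reference
#' oxidant pair (H-donation threshold from its O-H bond strength, electron
#' donation threshold from its electron-acceptor level).  Both axes are
#' kcal/mol; only relative placement is ever interpreted.
#'
#' @slot points data.frame with columns `species_id`, `BDE`, `IE`, `role`.
#' @slot bdeThreshold,ieThreshold numeric(1) reference lines.
#' @seealso [buildEHDAMA()], [classifySpecies()]
#' @exportClass EHDAMAMap
setClass("EHDAMAMap",
         representation(points = "data.frame",
                        bdeThreshold = "numeric", ieThreshold = "numeric"))

#' @describeIn EHDAMAMap-class display a short summary
#' @param object an `EHDAMAMap`
#' @export
setMethod("show", "EHDAMAMap", function(object) {
  cat(sprintf("EHDAMAMap: %d points; H-donation line at BDE = %.2f, SET line at IE = %.2f\n",
              nrow(object@points), object@bdeThreshold, object@ieThreshold))
})

# ---------------------------------------------------------------------------
# RateReport

#' RateReport: assembled rate-constant bookkeeping
#'
#' Per-channel activation/diffusion/apparent rate constants, per-species
#' totals, and (when speciation is supplied) the pH-weighted global rate
#' coefficient.  All bimolecular rate constants are in M^-1 s^-1.
#'
#' @slot channels data.frame, one row per retained channel with `k_TST`,
#'   `kappa`, `k_act`, `k_D`, `k_app` and a `diffusion_limited` flag.
#' @slot excluded data.frame, channels dropped by the thermodynamic
#'   feasibility filter or unavailable ("na") inputs, with a `reason` column.
#' @slot totals data.frame with `species`, `solvent`, `k_total`.
#' @slot global data.frame with `solvent`, `pH`, `k_global` (0 rows when no
#'   speciation was supplied).
#' @slot temperature numeric(1), K.
#' @seealso [assembleRates()], [globalRate()]
#' @exportClass RateReport
setClass("RateReport",
         representation(channels = "data.frame", excluded = "data.frame",
                        totals = "data.frame", global = "data.frame",
                        temperature = "numeric"))

#' @describeIn RateReport-class display a short summary
#' @param object a `RateReport`
#' @export
setMethod("show", "RateReport", function(object) {
  cat(sprintf("RateReport at %.2f K: %d channels (%d excluded)\n",
              object@temperature, nrow(object@channels), nrow(object@excluded)))
  if (nrow(object@totals)) {
    cat("  per-species totals (M^-1 s^-1):\n")
    print(object@totals, row.names = FALSE, digits = 3)
  }
  if (nrow(object@global)) {
    cat("  global:\n")
    print(object@global, row.names = FALSE, digits = 3)
  }
})
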