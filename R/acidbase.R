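#' Fitted-parameter regression coefficients for pKa estimation
#'
#' The bundled slope/intercept table mapping computed deprotonation free
#' energies to pKa by functional group (values fitted at the
#' M05-2X/6-311+G(d,p) level against experimental pKa's).
#'
#' @return data.frame with columns `group`, `m`, `C0`.
#' @examples fpaParameters()
#' @export
fpaParameters <- function() {
  data.frame(group = c("thiol", "phenol", "carboxylic_acid", "amine"),
             m = c(0.357, 0.316, 0.356, 0.464),
             C0 = c(-94.639, -81.497, -94.380, -121.000),
             stringsAsFactors = FALSE)
}

#' Estimate pKa from a deprotonation free energy
#'
#' Linear fitted-parameters estimate `pKa = m * dG_BA + C0`, where `dG_BA`
#' is the computed basicity free energy (kcal/mol) of the deprotonation and
#' the coefficients depend on the functional group being deprotonated.
#'
#' @param dG_BA deprotonation free energy, kcal/mol.
#' @param group one of the groups in `params` (thiol, phenol,
#'   carboxylic_acid, amine for the bundled table).
#' @param params coefficient table, see [fpaParameters()].
#' @return numeric pKa (vectorised over `dG_BA`).
#' @examples
#' pkaFromFPA(281.89, "phenol")  # about 7.58
#' @export
pkaFromFPA <- function(dG_BA, group, params = fpaParameters()) {
  i <- match(group, params$group)
  if (anyNA(i))
    stop("unknown functional group '", paste(group[is.na(i)], collapse = ", "),
         "'; known groups: ", paste(params$group, collapse = ", "))
  params$m[i] * dG_BA + params$C0[i]
}

.speciesNames <- function(nSpecies) {
  base <- c("neutral", "mono-anion", "di-anion", "tri-anion", "tetra-anion")
  if (nSpecies <= length(base)) base[seq_len(nSpecies)]
  else c(base, paste0("anion-", seq(length(base), nSpecies - 1L)))[seq_len(nSpecies)]
}

#' Construct an acid-base system
#'
#' @param compoundId compound identifier.
#' @param pka strictly increasing macroscopic pKa values.
#' @param speciesLabels optional labels for the `length(pka) + 1` protonation
#'   states; defaults to neutral, mono-anion, di-anion, ...
#' @param uncertainty stated pKa uncertainty (default 0.2 pKa units).
#' @return An [AcidBaseSystem-class] object.
#' @examples
#' acidBaseSystem("dCAF-16", c(3.33, 7.58, 11.92))
#' @export
acidBaseSystem <- function(compoundId, pka,
                           speciesLabels = .speciesNames(length(pka) + 1L),
                           uncertainty = 0.2) {
  new("AcidBaseSystem", compoundId = as.character(compoundId),
      pka = as.numeric(pka), speciesLabels = speciesLabels,
      uncertainty = uncertainty)
}

#' Molar fractions of the protonation states at a given pH
#'
#' Macroscopic successive-deprotonation (ladder) model: the fraction of the
#' k-times-deprotonated species is proportional to
#' `10^(k * pH - sum(pKa[1..k]))`, normalised over all states.  Computed in
#' log10 space so extreme ladders cannot overflow.
#'
#' @param system an [AcidBaseSystem-class].
#' @param pH the pH (default 7.4, physiological).
#' @return data.frame with columns `compound`, `pH`, `species`, `fraction`.
#' @examples
#' speciationFractions(acidBaseSystem("dCAF-16", c(3.33, 7.58, 11.92)), 7.4)
#' @export
speciationFractions <- function(system, pH = 7.4) {
  stopifnot(is(system, "AcidBaseSystem"), length(pH) == 1L)
  validObject(system)
  k <- seq_along(system@pka)
  logw <- c(0, k * pH - cumsum(system@pka))
  logw <- logw - max(logw)
  w <- 10^logw
  data.frame(compound = system@compoundId, pH = pH,
             species = system@speciesLabels, fraction = w / sum(w),
             stringsAsFactors = FALSE)
}

#' Speciation over a pH grid
#'
#' Evaluates [speciationFractions()] along a sorted pH grid, in a long
#' format suitable for distribution-diagram plotting or export.
#'
#' @param system an [AcidBaseSystem-class].
#' @param pHgrid sorted numeric vector of pH values.
#' @return data.frame with columns `compound`, `pH`, `species`, `fraction`.
#' @export
distributionProfile <- function(system, pHgrid = seq(0, 14, by = 0.1)) {
  if (is.unsorted(pHgrid)) stop("pH grid must be sorted")
  do.call(rbind, lapply(pHgrid, function(p) speciationFractions(system, p)))
}

#' Independent numeric equilibrium solver (cross-check oracle)
#'
#' Computes the same molar fractions as [speciationFractions()] but by a
#' brute-force route: mass-action ratios are built from the acid constants at
#' fixed proton activity and the mass-balance closure (fractions summing to
#' one) is solved numerically by root finding on the neutral-species
#' fraction.  Used to cross-validate the closed-form ladder model.
#'
#' @param pka strictly increasing pKa values.
#' @param pH the pH.
#' @return numeric vector of fractions, neutral species first.
#' @examples
#' equilibriumFractions(c(3.33, 7.58, 11.92), 7.4)
#' @export
equilibriumFractions <- function(pka, pH) {
  if (any(diff(pka) <= 0)) stop("pKa values must be strictly increasing")
  # mass action at fixed [H+]: c_k = c_0 * prod_{i<=k} (Ka_i / H)
  logRatios <- cumsum(-pka + pH)              # log10 of c_k / c_0
  f <- function(logc0) sum(10^(logc0 + c(0, logRatios))) - 1
  sol <- stats::uniroot(f, lower = -400, upper = 1, tol = 1e-15)
  10^(sol$root + c(0, logRatios))
}

#' Sensitivity of molar fractions to the stated pKa uncertainty
#'
#' Perturbs each pKa in turn by plus/minus the system's stated uncertainty
#' and reports the resulting change in every species' molar fraction,
#' bounding the effect of the +/- 0.2 pKa-unit uncertainty on the reported
#' speciation.
#'
#' @param system an [AcidBaseSystem-class].
#' @param pH the pH (default 7.4).
#' @param delta perturbation size; defaults to the system's uncertainty.
#' @return data.frame with columns `perturbed_pka`, `shift`, `species`,
#'   `fraction`, `delta_fraction`.
#' @export
speciationSensitivity <- function(system, pH = 7.4, delta = system@uncertainty) {
  base <- speciationFractions(system, pH)
  out <- list()
  for (i in seq_along(system@pka)) for (s in c(-delta, delta)) {
    p <- system@pka; p[i] <- p[i] + s
    if (any(diff(p) <= 0)) next  # perturbation would break the ladder order
    pert <- speciationFractions(acidBaseSystem(system@compoundId, p,
                                               system@speciesLabels,
                                               system@uncertainty), pH)
    out[[length(out) + 1L]] <- data.frame(
      perturbed_pka = i, shift = s, species = base$species,
      fraction = pert$fraction,
      delta_fraction = pert$fraction - base$fraction,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
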