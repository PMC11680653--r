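#' Bundled solvent viscosities
#'
#' The two study media: water (aqueous phase) and pentylethanoate (a lipid
#' mimic), with dynamic viscosities at 298.15 K.
#'
#' @return data.frame with columns `name`, `eta_Pa_s`, `context`.
#' @examples solventTable()
#' @export
solventTable <- function() {
  data.frame(name = c("water", "pentylethanoate"),
             eta_Pa_s = c(8.91e-4, 8.62e-4),
             context = c("aqueous", "lipid"),
             stringsAsFactors = FALSE)
}

#' Conventional transition-state-theory rate constant
#'
#' Eyring expression under a 1 M standard state:
#' `k = sigma * kappa * (kB*T/h) * exp(-dG_act / (R*T))` with the gas
#' constant `R = 1.98720e-3` kcal mol^-1 K^-1.  The result carries M^-1 s^-1
#' units when the activation free energy was referenced to the bimolecular
#' 1 M standard state.
#'
#' @param dG_act activation free energy, kcal/mol.
#' @param temperature K (default 298.15).
#' @param sigma reaction path degeneracy (>= 1).
#' @param kappa tunneling correction (>= 1).
#' @return rate constant (vectorised over `dG_act`).
#' @examples
#' tstRate(15.20)          # about 44.7
#' tstRate(0)              # kB*T/h = 6.212e12
#' @export
tstRate <- function(dG_act, temperature = 298.15, sigma = 1, kappa = 1) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  if (any(sigma < 1)) stop("sigma must be >= 1")
  if (any(kappa < 1)) stop("kappa must be >= 1: tunneling cannot slow a reaction")
  sigma * kappa * (.kB * temperature / .h) *
    exp(-dG_act / (.Rkcal * temperature))
}

#' Wigner tunneling correction
#'
#' Lowest-order parabolic-barrier correction
#' `kappa = 1 + (1/24) * (h*c*nu / (kB*T))^2` for an imaginary wavenumber
#' `nu` (cm^-1).
#'
#' @param nu_cm magnitude of the imaginary wavenumber, cm^-1.
#' @param temperature K.
#' @return kappa (>= 1).
#' @examples
#' wignerKappa(1500)  # about 3.18 at 298.15 K
#' @export
wignerKappa <- function(nu_cm, temperature = 298.15) {
  if (any(nu_cm < 0)) stop("imaginary wavenumber must be positive")
  u <- .h * .c_cm * nu_cm / (.kB * temperature)
  1 + u^2 / 24
}

# Numerically stable cosh(x)/cosh(y) for large arguments.
.coshRatio <- function(x, y) {
  exp(abs(x) - abs(y)) * (1 + exp(-2 * abs(x))) / (1 + exp(-2 * abs(y)))
}

#' Transmission probability through an asymmetric Eckart barrier
#'
#' Exact quantum transmission probability `P(E)` for the one-dimensional
#' asymmetric Eckart barrier fitted to the forward barrier `V1`, reverse
#' barrier `V2` and the magnitude of the imaginary wavenumber at the saddle
#' point.  Energies are measured from the reactant asymptote.  Evaluated in
#' log space so large barrier/frequency ratios cannot overflow.
#'
#' @param E total energy, kcal/mol (vectorised).
#' @param V1,V2 forward and reverse barrier heights, kcal/mol (> 0).
#' @param nu_cm imaginary wavenumber, cm^-1.
#' @return transmission probability in `[0, 1]`; zero below the higher
#'   asymptote.
#' @export
eckartTransmission <- function(E, V1, V2, nu_cm) {
  if (V1 <= 0 || V2 <= 0) stop("barriers must be positive")
  if (nu_cm <= 0) stop("imaginary wavenumber must be positive")
  hnu <- nu_cm * .wavenumber2kcal
  a1 <- 2 * pi * V1 / hnu
  a2 <- 2 * pi * V2 / hnu
  Cinv <- 1 / (1 / sqrt(a1) + 1 / sqrt(a2))
  Emin <- max(0, V1 - V2)
  P <- numeric(length(E))
  ok <- E > Emin
  if (!any(ok)) return(P)
  a <- 2 * sqrt(2 * pi * E[ok] / hnu) * Cinv
  b <- 2 * sqrt(2 * pi * (E[ok] - V1 + V2) / hnu) * Cinv
  d2 <- a1 * a2 - pi^2 / 4
  # P = (1 - cosh(a-b)/cosh(a+b)) / (1 + cosh(d)/cosh(a+b)), where
  # cosh(d) -> cos(2*sqrt(-d2)) when the barrier is too thin/low for the
  # hyperbolic regime; ratios evaluated in log space to avoid overflow
  num <- 1 - .coshRatio(a - b, a + b)
  ratio <- if (d2 >= 0) .coshRatio(2 * sqrt(d2), a + b) else
    cos(2 * sqrt(-d2)) * 2 * exp(-(a + b)) / (1 + exp(-2 * (a + b)))
  P[ok] <- num / (1 + ratio)
  pmin(pmax(P, 0), 1)
}

#' Eckart zero-curvature tunneling correction
#'
#' Boltzmann average of the ratio of the quantum and classical transmission
#' probabilities through an asymmetric Eckart barrier fitted to the forward
#' and reverse barriers and the imaginary wavenumber:
#' `kappa = exp(V1/RT)/RT * integral P(E) exp(-E/RT) dE` over energies above
#' the higher asymptote.  The quadrature is adaptive; the result is floored
#' at 1 (a pure transmission treatment cannot make the reaction slower than
#' classical in this bookkeeping).
#'
#' @param dG_forward,dG_reverse forward/reverse barriers, kcal/mol.
#' @param nu_cm imaginary wavenumber, cm^-1.
#' @param temperature K.
#' @return kappa (>= 1).
#' @examples
#' eckartKappa(10, 10, 1500)
#' @export
eckartKappa <- function(dG_forward, dG_reverse, nu_cm, temperature = 298.15) {
  if (is.na(dG_reverse)) stop("incomplete tunneling spec: reverse barrier required")
  RT <- .Rkcal * temperature
  Emin <- max(0, dG_forward - dG_reverse)
  integrand <- function(t)  # t = E - Emin
    eckartTransmission(Emin + t, dG_forward, dG_reverse, nu_cm) *
      exp(-(Emin + t - dG_forward) / RT) / RT
  upper <- dG_forward - Emin + 40 * RT
  q <- stats::integrate(integrand, 0, upper, rel.tol = 1e-9,
                        subdivisions = 400L)
  max(1, q$value)
}

#' Tunneling correction dispatcher
#'
#' @param method one of `"none"`, `"wigner"`, `"eckart_zct"`.
#' @param dG_forward forward barrier, kcal/mol.
#' @param nu_cm imaginary wavenumber, cm^-1 (required unless `method` is
#'   `"none"`).
#' @param dG_reverse reverse barrier, kcal/mol (required for `eckart_zct`).
#' @param temperature K.
#' @return kappa (>= 1).
#' @export
tunnelingKappa <- function(method = c("none", "wigner", "eckart_zct"),
                           dG_forward = NA, nu_cm = NA, dG_reverse = NA,
                           temperature = 298.15) {
  method <- match.arg(method)
  if (method == "none") return(1)
  if (!is.finite(nu_cm) || nu_cm <= 0)
    stop("imaginary wavenumber must be positive for tunneling method ", method)
  switch(method,
         wigner = wignerKappa(nu_cm, temperature),
         eckart_zct = eckartKappa(dG_forward, dG_reverse, nu_cm, temperature))
}

#' Marcus-theory activation barrier for electron transfer
#'
#' `dG_act = (lambda/4) * (1 + dG_SET/lambda)^2` with reorganisation energy
#' `lambda` (kcal/mol).
#'
#' @param dG_SET electron-transfer reaction free energy, kcal/mol.
#' @param lambda reorganisation energy, kcal/mol (> 0).
#' @return activation barrier, kcal/mol (vectorised).
#' @examples
#' marcusBarrier(10, 40)  # 15.625
#' @export
marcusBarrier <- function(dG_SET, lambda) {
  if (any(lambda <= 0)) stop("reorganisation energy must be positive")
  (lambda / 4) * (1 + dG_SET / lambda)^2
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = kB*T / (6*pi*eta*a)` for a spherical solute of radius `a` in a
#' solvent of viscosity `eta`.
#'
#' @param temperature K.
#' @param eta solvent viscosity, Pa s.
#' @param radius solute radius, m.
#' @return D, m^2/s.
#' @examples
#' diffusionCoefficient(298.15, 8.91e-4, 2e-10)  # about 1.23e-9
#' @export
diffusionCoefficient <- function(temperature = 298.15, eta, radius) {
  if (any(radius <= 0)) stop("radius must be positive")
  if (any(eta <= 0)) stop("viscosity must be positive")
  .kB * temperature / (6 * pi * eta * radius)
}

#' Smoluchowski diffusion-limited rate constant
#'
#' Steady-state encounter rate `k_D = 4*pi*R*D_AB*NA` for an irreversible
#' bimolecular diffusion-controlled reaction, converted to M^-1 s^-1.
#'
#' @param reactionDistance encounter distance R, m.
#' @param D_AB mutual diffusion coefficient `D_A + D_B`, m^2/s.
#' @return k_D, M^-1 s^-1.
#' @examples
#' smoluchowskiRate(4e-10, 2.45e-9)  # about 7.4e9
#' @export
smoluchowskiRate <- function(reactionDistance, D_AB) {
  if (any(reactionDistance <= 0) || any(D_AB <= 0))
    stop("reaction distance and mutual diffusion coefficient must be positive")
  4 * pi * reactionDistance * D_AB * .NA * 1000
}

#' Collins-Kimball apparent rate constant
#'
#' Interpolates between activation control and diffusion control:
#' `k_app = k_D * k_act / (k_D + k_act)`.  Barrier-less channels pass
#' `k_act = Inf` and collapse to the diffusion limit `k_app = k_D`.
#'
#' @param k_act activation-controlled (TST) rate constant, M^-1 s^-1; may be
#'   `Inf` for barrier-less channels.
#' @param k_D diffusion-limited rate constant, M^-1 s^-1.
#' @return apparent rate constant, M^-1 s^-1 (vectorised).
#' @examples
#' apparentRate(1e5, 8e9)   # activation-controlled
#' apparentRate(Inf, 8e9)   # diffusion-controlled
#' @export
apparentRate <- function(k_act, k_D) {
  if (any(k_act < 0) || any(k_D < 0)) stop("rate constants must be >= 0")
  if (any(k_act == 0 & k_D == 0)) stop("undefined rate: both k_act and k_D are zero")
  ifelse(is.infinite(k_act), k_D, k_D * k_act / (k_D + k_act))
}

#' Sum channel rates into a per-species total
#'
#' @param k_app vector of apparent per-channel rate constants sharing one
#'   compound, species and solvent; alternatively a data.frame with a
#'   `k_app` column plus `species`/`solvent` columns which are validated to
#'   be homogeneous.
#' @return the arithmetic sum.
#' @examples
#' speciesTotalRate(c(1.69e5, 4.43e5))  # 6.12e5
#' @export
speciesTotalRate <- function(k_app) {
  if (is.data.frame(k_app)) {
    for (col in intersect(c("compound", "species", "solvent"), names(k_app)))
      if (length(unique(k_app[[col]])) > 1L)
        stop("mixed ", col, " in one total: ",
             paste(unique(k_app[[col]]), collapse = ", "))
    k_app <- k_app$k_app
  }
  sum(k_app)
}

#' pH-weighted global rate coefficient
#'
#' Weights per-species total rate constants by the molar fractions of the
#' protonation states at the working pH:
#' `k_global = sum_species Mf(species) * k_total(species)`.
#'
#' @param totals named numeric vector of per-species `k_total`, or a
#'   data.frame with `species` and `k_total` columns.
#' @param fractions named numeric vector of molar fractions, or a speciation
#'   data.frame with `species` and `fraction` columns (as from
#'   [speciationFractions()]).
#' @return k_global, M^-1 s^-1.
#' @examples
#' globalRate(c(neutral = 1.97e4, `mono-anion` = 4.11e4, `di-anion` = 7.86e9),
#'            c(neutral = 1e-4, `mono-anion` = 0.7764, `di-anion` = 0.2235))
#' @export
globalRate <- function(totals, fractions) {
  if (is.data.frame(totals)) totals <- setNames(totals$k_total, totals$species)
  if (is.data.frame(fractions)) fractions <- setNames(fractions$fraction, fractions$species)
  miss <- setdiff(names(totals), names(fractions))
  if (length(miss))
    stop("species mismatch: no molar fraction for ", paste(miss, collapse = ", "))
  sum(fractions[names(totals)] * totals)
}

#' Assemble a rate report from a channel table
#'
#' Runs the full per-channel bookkeeping: thermodynamic feasibility
#' filtering, tunneling corrections, TST rates, Stokes-Einstein/Smoluchowski
#' diffusion limits and Collins-Kimball apparent rate constants; then
#' aggregates per-species totals and, when speciation is supplied,
#' pH-weighted global rate coefficients.
#'
#' The channel table needs columns `compound`, `species`, `mechanism`,
#' `site`, `solvent`, `dG_rxn`, `dG_act`, `barrierless`; optional columns
#' `sigma` (default 1), `tunneling_method` (default "none"), `nu_imag_cm`,
#' `dG_act_reverse`, `radius_A` (solute radius, Angstrom, default
#' `soluteRadius_A`).  A channel with `barrierless = TRUE` (or
#' `dG_act <= 0`) is treated as diffusion-controlled.  Channels with
#' `dG_rxn > 0` are excluded when `feasibilityFilter` is on (the default),
#' mirroring the exclusion of endergonic paths from viable-channel rate
#' assembly; channels with unavailable (`NA`) barriers are excluded and
#' reported.
#'
#' @param channels channel data.frame (see Details).
#' @param solvents solvent table, see [solventTable()].
#' @param temperature K.
#' @param speciation optional speciation data.frame with columns `compound`,
#'   `species`, `fraction` (and `pH`), used for the global coefficients.
#' @param feasibilityFilter drop endergonic channels (default `TRUE`).
#' @param soluteRadius_A default solute radius, Angstrom.
#' @param radicalRadius_A radius of the radical partner, Angstrom.
#' @return A [RateReport-class] object.
#' @export
assembleRates <- function(channels, solvents = solventTable(),
                          temperature = 298.15, speciation = NULL,
                          feasibilityFilter = TRUE,
                          soluteRadius_A = 3.5, radicalRadius_A = 2.0) {
  need <- c("compound", "species", "mechanism", "site", "solvent",
            "dG_rxn", "dG_act", "barrierless")
  miss <- setdiff(need, names(channels))
  if (length(miss)) stop("channel table lacks column(s): ", paste(miss, collapse = ", "))
  ch <- as.data.frame(channels)
  if (is.null(ch$sigma)) ch$sigma <- 1L
  ch$sigma[is.na(ch$sigma)] <- 1L
  if (is.null(ch$tunneling_method)) ch$tunneling_method <- "none"
  ch$tunneling_method[is.na(ch$tunneling_method)] <- "none"
  if (is.null(ch$nu_imag_cm)) ch$nu_imag_cm <- NA_real_
  if (is.null(ch$dG_act_reverse)) ch$dG_act_reverse <- NA_real_
  if (is.null(ch$radius_A)) ch$radius_A <- soluteRadius_A
  ch$radius_A[is.na(ch$radius_A)] <- soluteRadius_A
  ch$barrierless <- isTRUE_v(ch$barrierless)
  if (any(ch$barrierless & !is.na(ch$dG_act)))
    stop("barrierless flag and a finite dG_act are mutually exclusive")

  reason <- rep(NA_character_, nrow(ch))
  if (feasibilityFilter)
    reason[!is.na(ch$dG_rxn) & ch$dG_rxn > 0] <- "endergonic"
  reason[is.na(reason) & !ch$barrierless & is.na(ch$dG_act)] <- "barrier unavailable"
  excluded <- cbind(ch[!is.na(reason), , drop = FALSE],
                    reason = reason[!is.na(reason)])
  keep <- ch[is.na(reason), , drop = FALSE]
  if (nrow(excluded))
    message(nrow(excluded), " channel(s) excluded from rate assembly (",
            paste(unique(excluded$reason), collapse = "; "), ")")

  n <- nrow(keep)
  kTST <- kappa <- kact <- kD <- kapp <- rep(NA_real_, n)
  difflim <- logical(n)
  eta <- setNames(solvents$eta_Pa_s, solvents$name)
  for (i in seq_len(n)) {
    row <- keep[i, ]
    if (!row$solvent %in% names(eta))
      stop("unknown solvent '", row$solvent, "'; known: ",
           paste(names(eta), collapse = ", "))
    DA <- diffusionCoefficient(temperature, eta[[row$solvent]], row$radius_A * 1e-10)
    DB <- diffusionCoefficient(temperature, eta[[row$solvent]], radicalRadius_A * 1e-10)
    kD[i] <- smoluchowskiRate((row$radius_A + radicalRadius_A) * 1e-10, DA + DB)
    if (row$barrierless || (!is.na(row$dG_act) && row$dG_act <= 0)) {
      kact[i] <- Inf; kappa[i] <- NA_real_
    } else {
      kappa[i] <- tunnelingKappa(row$tunneling_method, row$dG_act,
                                 row$nu_imag_cm, row$dG_act_reverse,
                                 temperature)
      kTST[i] <- tstRate(row$dG_act, temperature, row$sigma, 1)
      kact[i] <- kTST[i] * kappa[i]
    }
    kapp[i] <- apparentRate(kact[i], kD[i])
    difflim[i] <- !is.finite(kact[i]) || kD[i] < kact[i]
  }
  keep$k_TST <- kTST; keep$kappa <- kappa; keep$k_act <- kact
  keep$k_D <- kD; keep$k_app <- kapp; keep$diffusion_limited <- difflim

  totals <- if (n) {
    agg <- stats::aggregate(k_app ~ compound + species + solvent, keep, sum)
    names(agg)[names(agg) == "k_app"] <- "k_total"
    agg
  } else data.frame(compound = character(), species = character(),
                    solvent = character(), k_total = numeric())

  global <- data.frame(compound = character(), solvent = character(),
                       pH = numeric(), k_global = numeric())
  if (!is.null(speciation) && nrow(totals)) {
    pH <- if ("pH" %in% names(speciation)) unique(speciation$pH) else NA_real_
    for (cmp in unique(totals$compound)) for (sv in unique(totals$solvent)) {
      tt <- totals[totals$compound == cmp & totals$solvent == sv, ]
      sp <- speciation[speciation$compound == cmp, ]
      if (!nrow(tt) || !nrow(sp)) next
      kg <- globalRate(setNames(tt$k_total, tt$species),
                       setNames(sp$fraction, sp$species))
      global <- rbind(global, data.frame(compound = cmp, solvent = sv,
                                         pH = pH[1], k_global = kg))
    }
  }
  new("RateReport", channels = keep,
      excluded = if (nrow(excluded)) excluded else
        cbind(ch[0, , drop = FALSE], reason = character()),
      totals = totals, global = global, temperature = temperature)
}

# vectorised truthiness helper: NA -> FALSE
isTRUE_v <- function(x) !is.na(x) & as.logical(x)
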