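# Synthetic surrogate for the quantum-chemistry stage: analytic IRC
# profiles with closed-form critical points, channel tables with known
# aggregate rate constants, reference descriptor cohorts, and random acid
# ladders with oracle-solved fractions.  Every generator is deterministic
# under a fixed seed.

# run expr with a local RNG state seeded by `seed` (NULL = use current state)
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate an analytic single-barrier IRC profile with known ground truth
#'
#' Samples a sech-squared profile `V = E0 / cosh(xi/L)^2` when the
#' asymmetry `delta` is zero, otherwise an asymmetric Eckart-type profile
#' `V = A*y/(1+y) + B*y/(1+y)^2` with `y = exp(xi/L)`, `A = delta` (the
#' reaction energy) and `B` chosen so the forward barrier is `E0`.  Both
#' families have closed-form critical points: the force extrema of the
#' sech-squared barrier sit at `xi = -+ L*artanh(1/sqrt(3))` where the
#' energy splits 2/3 (preparation) to 1/3 (transition), and for the Eckart
#' family the inflection points solve a quadratic in `y`.  Optional Gaussian
#' noise is added after annotation; generation is retried when noise breaks
#' the single-barrier invariant.
#'
#' @param E0 forward barrier height, kcal/mol.
#' @param delta reaction energy (product asymptote minus reactant asymptote),
#'   kcal/mol; must be < `E0`.
#' @param L width parameter (reaction-coordinate units).
#' @param n grid size (>= 7).
#' @param halfWidth half-extent of the grid around the barrier, in units of
#'   `L`.
#' @param noiseSd additive Gaussian noise sd, kcal/mol.
#' @param seed optional RNG seed (only used when `noiseSd > 0`).
#' @return list with `profile` (an [IRCProfile-class]), and `truth`: a list
#'   holding `alpha`, `beta`, `gamma` and the asymptotic zone energies
#'   (`prep_forward`, `transition_forward`, `act_forward`, `prep_reverse`,
#'   `transition_reverse`, `act_reverse`).
#' @examples
#' g <- makeIrcProfile(E0 = 10, L = 1)
#' g$truth$prep_forward  # 2/3 of the barrier
#' @export
makeIrcProfile <- function(E0 = 10, delta = 0, L = 1, n = 201L,
                           halfWidth = 12, noiseSd = 0, seed = NULL) {
  stopifnot(E0 > 0, n >= 7L, noiseSd >= 0, L > 0)
  if (delta >= E0) stop("asymmetry must be smaller than the barrier height")
  if (delta == 0) {
    beta <- 0
    a0 <- atanh(1 / sqrt(3)) * L
    alpha <- -a0; gamma <- a0
    Vfun <- function(xi) E0 / cosh(xi / L)^2
    prepF <- 2 / 3 * E0; actF <- E0
    prepR <- 2 / 3 * E0; actR <- E0
  } else {
    A <- delta
    B <- (sqrt(E0) + sqrt(E0 - A))^2
    Vy <- function(y) A * y / (1 + y) + B * y / (1 + y)^2
    beta <- L * log((A + B) / (B - A))
    disc <- sqrt(3 * B^2 + A^2)
    alpha <- L * log((2 * B - disc) / (B - A))
    gamma <- L * log((2 * B + disc) / (B - A))
    Vfun <- function(xi) Vy(exp(xi / L))
    prepF <- Vy(exp(alpha / L)); actF <- E0
    prepR <- Vy(exp(gamma / L)) - A; actR <- E0 - A
  }
  truth <- list(alpha = alpha, beta = beta, gamma = gamma,
                prep_forward = prepF, transition_forward = actF - prepF,
                act_forward = actF,
                prep_reverse = prepR, transition_reverse = actR - prepR,
                act_reverse = actR,
                E0 = E0, delta = delta, L = L)
  xi <- seq(beta - halfWidth * L, beta + halfWidth * L, length.out = n)
  V <- Vfun(xi)
  .withSeed(seed, {
    for (try in 1:20) {
      Vn <- V + if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else 0
      prof <- ircProfile(xi, Vn)
      # the barrier must stand clear of the noise floor, not just be an argmax
      if (singleBarrier(prof) &&
          max(Vn) - max(Vn[1], Vn[n]) > 10 * noiseSd)
        return(list(profile = prof, truth = truth))
    }
    stop("noise sd too large: could not generate a valid single-barrier profile")
  })
}

#' Generate a reaction-channel table with known aggregate rates
#'
#' Emulates the structure of a QM-derived channel table for one compound
#' reacting with a peroxyl-type radical: formal hydrogen-atom-transfer
#' channels (exergonic, Eckart tunneling specs), electron-transfer channels
#' (barriers from Marcus theory with a drawn reorganisation energy), and
#' radical-adduct-formation channels drawn endergonic so the thermodynamic
#' feasibility filter removes them, across the neutral/mono-anion/di-anion
#' species in water and pentylethanoate.  One barrier-less di-anion channel
#' is included when `barrierless = TRUE`.  The expected per-channel rates,
#' per-species totals and the pH-weighted global coefficient are computed
#' internally from the same closed forms, so the assembly pipeline can be
#' round-trip tested.
#'
#' @param compound compound id.
#' @param nSitesHAT number of H-donor sites.
#' @param nSitesRAF number of addition sites.
#' @param barrierless include a barrier-less di-anion channel.
#' @param pH working pH for the speciation and global coefficient.
#' @param temperature K.
#' @param radicalRadius_A radical radius for the diffusion correction.
#' @param seed RNG seed.
#' @return list with `channels` (data.frame), `speciation` (data.frame),
#'   and `truth` (list with `channels` incl. expected `k_app`, `totals`,
#'   `global`).
#' @export
makeChannelTable <- function(compound = "synA", nSitesHAT = 2L, nSitesRAF = 3L,
                             barrierless = TRUE, pH = 7.4,
                             temperature = 298.15, radicalRadius_A = 2.0,
                             seed = NULL) {
  .withSeed(seed, {
    species <- c("neutral", "mono-anion", "di-anion")
    solvents <- c("water", "pentylethanoate")
    rows <- list()
    add <- function(r) rows[[length(rows) + 1L]] <<- r
    for (sv in solvents) for (sp in species) {
      for (s in seq_len(nSitesHAT)) {
        bl <- barrierless && sp == "di-anion" && s == nSitesHAT
        dG <- stats::runif(1, -14, -1)
        act <- if (bl) NA_real_ else stats::runif(1, 6, 18)
        add(data.frame(compound = compound, species = sp, mechanism = "f-HAT",
                       site = paste0("O", s), solvent = sv, dG_rxn = dG,
                       dG_act = act, barrierless = bl,
                       sigma = sample(1:2, 1),
                       tunneling_method = if (bl) "none" else "eckart_zct",
                       nu_imag_cm = if (bl) NA_real_ else stats::runif(1, 900, 2200),
                       dG_act_reverse = if (bl) NA_real_ else act - dG,
                       radius_A = round(stats::runif(1, 3.0, 4.5), 2)))
      }
      for (s in seq_len(nSitesRAF))
        add(data.frame(compound = compound, species = sp, mechanism = "RAF",
                       site = paste0("C", s), solvent = sv,
                       dG_rxn = stats::runif(1, 1, 15), dG_act = stats::runif(1, 8, 20),
                       barrierless = FALSE, sigma = 1L, tunneling_method = "none",
                       nu_imag_cm = NA_real_, dG_act_reverse = NA_real_,
                       radius_A = round(stats::runif(1, 3.0, 4.5), 2)))
      lambda <- stats::runif(1, 10, 40)
      dG_SET <- stats::runif(1, -2, 20)
      add(data.frame(compound = compound, species = sp, mechanism = "SET",
                     site = "SET", solvent = sv, dG_rxn = dG_SET,
                     dG_act = marcusBarrier(dG_SET, lambda), barrierless = FALSE,
                     sigma = 1L, tunneling_method = "none",
                     nu_imag_cm = NA_real_, dG_act_reverse = NA_real_,
                     radius_A = round(stats::runif(1, 3.0, 4.5), 2)))
    }
    channels <- do.call(rbind, rows)

    pka <- sort(stats::runif(2, 2, 12)); while (diff(pka) < 1) pka <- sort(stats::runif(2, 2, 12))
    system <- acidBaseSystem(compound, pka, .speciesNames(3L))
    frac <- equilibriumFractions(pka, pH)
    speciation <- data.frame(compound = compound, pH = pH,
                             species = .speciesNames(3L), fraction = frac,
                             stringsAsFactors = FALSE)

    # expected values straight from the closed forms
    eta <- setNames(solventTable()$eta_Pa_s, solventTable()$name)
    exp_k <- function(row) {
      DA <- diffusionCoefficient(temperature, eta[[row$solvent]], row$radius_A * 1e-10)
      DB <- diffusionCoefficient(temperature, eta[[row$solvent]], radicalRadius_A * 1e-10)
      kD <- smoluchowskiRate((row$radius_A + radicalRadius_A) * 1e-10, DA + DB)
      if (row$barrierless) return(kD)
      kap <- tunnelingKappa(row$tunneling_method, row$dG_act, row$nu_imag_cm,
                            row$dG_act_reverse, temperature)
      apparentRate(tstRate(row$dG_act, temperature, row$sigma, kap), kD)
    }
    viable <- channels[channels$dG_rxn <= 0, , drop = FALSE]
    viable$k_app <- vapply(seq_len(nrow(viable)),
                           function(i) exp_k(viable[i, ]), numeric(1))
    totals <- stats::aggregate(k_app ~ compound + species + solvent, viable, sum)
    names(totals)[names(totals) == "k_app"] <- "k_total"
    global <- do.call(rbind, lapply(solvents, function(sv) {
      tt <- totals[totals$solvent == sv, ]
      data.frame(compound = compound, solvent = sv, pH = pH,
                 k_global = globalRate(setNames(tt$k_total, tt$species),
                                       setNames(frac, speciation$species)))
    }))
    list(channels = channels, speciation = speciation, system = system,
         truth = list(channels = viable, totals = totals, global = global))
  })
}

#' Generate a synthetic reference descriptor cohort
#'
#' Draws a cohort of descriptor records emulating a reference set of
#' compounds in clinical use: ADME descriptors from normal distributions
#' centred on typical oral-drug values, LD50 from a log-normal centred on
#' 1142.87 mg/kg (the reference-set average echoed by the scoring layer),
#' Ames mutagenicity probabilities and a 1-100 synthetic-accessibility
#' score.
#'
#' @param n cohort size (default 54).
#' @param means,sds optional named overrides of the generating means/sds for
#'   the continuous properties (`MW`, `logP`, `MR`, `PSA`, `SA`).
#' @param seed RNG seed.
#' @return descriptor data.frame in the [computeDescriptors()] schema.
#' @export
makeReferenceDescriptors <- function(n = 54L, means = NULL, sds = NULL,
                                     seed = NULL) {
  stopifnot(n >= 2L)
  m <- c(MW = 320, logP = 2.5, MR = 90, PSA = 75, SA = 55)
  s <- c(MW = 80, logP = 1.2, MR = 25, PSA = 30, SA = 15)
  if (!is.null(means)) m[names(means)] <- means
  if (!is.null(sds)) s[names(sds)] <- sds
  if (any(s < 0)) stop("generating sds must be >= 0")
  .withSeed(seed, {
    sdlog <- 0.5
    data.frame(
      id = sprintf("ref%03d", seq_len(n)),
      smiles = NA_character_,
      HBD = pmin(pmax(round(stats::rnorm(n, 2.2, 1.2)), 0L), 8L),
      HBA = pmax(round(stats::rnorm(n, 5, 2)), 0L),
      MW = pmax(stats::rnorm(n, m["MW"], s["MW"]), 60),
      logP = stats::rnorm(n, m["logP"], s["logP"]),
      MR = pmax(stats::rnorm(n, m["MR"], s["MR"]), 10),
      AtX = pmax(round(stats::rnorm(n, 23, 6)), 5L),
      RB = pmax(round(stats::rnorm(n, 5, 2.5)), 0L),
      PSA = pmax(stats::rnorm(n, m["PSA"], s["PSA"]), 3),
      LD50 = stats::rlnorm(n, log(1142.87) - sdlog^2 / 2, sdlog),
      ames = stats::runif(n, 0, 0.4),
      SA = pmin(pmax(stats::rnorm(n, m["SA"], s["SA"]), 1), 100),
      stringsAsFactors = FALSE)
  })
}

#' Generate a random acid-base ladder with oracle-solved fractions
#'
#' Draws a strictly increasing macroscopic pKa ladder (2-4 steps by default)
#' and solves its speciation at the working pH with the independent numeric
#' equilibrium solver, so the closed-form ladder model can be tested against
#' it.
#'
#' @param nSteps number of deprotonation steps, or `NULL` to draw 2-4.
#' @param pH working pH.
#' @param seed RNG seed.
#' @return list with `system` (an [AcidBaseSystem-class]), `pH`, and
#'   `expected` (named fractions from [equilibriumFractions()]).
#' @export
makeSpeciationCase <- function(nSteps = NULL, pH = 7.4, seed = NULL) {
  .withSeed(seed, {
    if (is.null(nSteps)) nSteps <- sample(2:4, 1)
    pka <- cumsum(c(stats::runif(1, 1.5, 5), stats::runif(nSteps - 1, 1.5, 4.5)))
    system <- acidBaseSystem(paste0("syn-", paste(round(pka, 2), collapse = "/")),
                             pka)
    list(system = system, pH = pH,
         expected = setNames(equilibriumFractions(pka, pH),
                             system@speciesLabels))
  })
}
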