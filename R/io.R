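.mechanisms <- c("f-HAT", "SET", "RAF")

#' Pipeline run configuration
#'
#' Collects the cross-stage settings with their documented defaults
#' (298.15 K, pH 7.4, the bundled solvent table, unit flags, score weights
#' and thresholds).  Any override is echoed so a run log records the
#' deviations from the defaults.
#'
#' @param temperature K.
#' @param pH working pH.
#' @param solvents solvent table (see [solventTable()]).
#' @param ircUnits `"kcal/mol"` or `"hartree"`.
#' @param weights score weights (see [scoreWeights()]).
#' @param zThreshold elimination-score flag threshold.
#' @param selectionThresholds named numeric `reference`/`parent`.
#' @param feasibilityFilter drop endergonic channels in the kinetics stage.
#' @param radicalRadius_A radical radius, Angstrom.
#' @param outDir output directory.
#' @param seed RNG seed for the synthetic generators.
#' @param quiet suppress the override echo.
#' @return named list of settings.
#' @examples runConfig(pH = 5.0)
#' @export
runConfig <- function(temperature = 298.15, pH = 7.4, solvents = solventTable(),
                      ircUnits = c("kcal/mol", "hartree"),
                      weights = scoreWeights(), zThreshold = 2,
                      selectionThresholds = c(reference = 1.0, parent = 1.0),
                      feasibilityFilter = TRUE, radicalRadius_A = 2.0,
                      outDir = ".", seed = NULL, quiet = FALSE) {
  ircUnits <- match.arg(ircUnits)
  cfg <- list(temperature = temperature, pH = pH, solvents = solvents,
              ircUnits = ircUnits, weights = weights, zThreshold = zThreshold,
              selectionThresholds = selectionThresholds,
              feasibilityFilter = feasibilityFilter,
              radicalRadius_A = radicalRadius_A, outDir = outDir, seed = seed)
  if (!quiet) {
    defaults <- list(temperature = 298.15, pH = 7.4, zThreshold = 2,
                     ircUnits = "kcal/mol", radicalRadius_A = 2.0)
    for (nm in names(defaults))
      if (!identical(cfg[[nm]], defaults[[nm]]))
        message("config override: ", nm, " = ", format(cfg[[nm]]))
  }
  cfg
}

#' Read a validated reaction-channel table
#'
#' Reads a channel CSV (columns `compound`, `species`, `mechanism`, `site`,
#' `solvent`, `dG_rxn`, `dG_act`, optional `sigma`, `tunneling_method`,
#' `nu_imag_cm`, `dG_act_reverse`, `radius_A`).  The token `barrierless` in
#' the `dG_act` column marks a barrier-less channel; `na` cells parse to
#' missing values, and channels whose barrier is missing are later excluded
#' from rate assembly with a logged notice.  Rows with unknown mechanism or
#' species tokens are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return validated data.frame ready for [assembleRates()].
#' @export
readChannelTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("na", "NA", ""))
  need <- c("compound", "species", "mechanism", "site", "solvent",
            "dG_rxn", "dG_act")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  lineno <- seq_len(nrow(raw)) + 1L  # header is line 1
  errs <- character()
  badMech <- !raw$mechanism %in% .mechanisms
  if (any(badMech))
    errs <- c(errs, sprintf("line %d: unknown mechanism '%s'",
                            lineno[badMech], raw$mechanism[badMech]))
  knownSpecies <- .speciesNames(5L)
  badSp <- !raw$species %in% knownSpecies
  if (any(badSp))
    errs <- c(errs, sprintf("line %d: unknown species '%s'",
                            lineno[badSp], raw$species[badSp]))
  if (length(errs)) stop("schema error in ", path, ":\n  ",
                         paste(errs, collapse = "\n  "))
  bl <- !is.na(raw$dG_act) & tolower(trimws(raw$dG_act)) == "barrierless"
  raw$barrierless <- bl
  raw$dG_act <- suppressWarnings(as.numeric(ifelse(bl, NA, raw$dG_act)))
  for (col in c("dG_rxn", "nu_imag_cm", "dG_act_reverse", "radius_A", "sigma"))
    if (col %in% names(raw)) raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  raw
}

#' Read a solvent viscosity table
#'
#' @param path CSV with columns `name`, `eta_Pa_s`.
#' @return data.frame usable as the `solvents` argument of
#'   [assembleRates()].
#' @export
readSolventTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "eta_Pa_s") %in% names(tab)))
    stop("schema error in ", path, ": need columns name, eta_Pa_s")
  if (any(tab$eta_Pa_s <= 0)) stop("viscosities must be positive")
  tab
}

#' Read a pKa table into acid-base systems
#'
#' @param path CSV with column `compound` followed by `pka1`, `pka2`, ...
#'   (blank/`na` cells for compounds with fewer steps).
#' @return named list of [AcidBaseSystem-class] objects.
#' @export
readPkaTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("na", "NA", ""))
  pkcols <- grep("^pka", names(tab), value = TRUE)
  if (!"compound" %in% names(tab) || !length(pkcols))
    stop("schema error in ", path, ": need 'compound' and pka1.. columns")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    pka <- stats::na.omit(as.numeric(tab[i, pkcols]))
    acidBaseSystem(tab$compound[i], pka)
  })
  names(out) <- tab$compound
  out
}

#' Read a two-column IRC table
#'
#' @param path whitespace- or comma-separated two-column text file
#'   (reaction coordinate, potential energy).
#' @param units energy units of the file.
#' @return An [IRCProfile-class].
#' @export
readIrcTable <- function(path, units = c("kcal/mol", "hartree")) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#",
                           col.names = c("xi", "energy"))
  ircProfile(tab$xi, tab$energy, match.arg(units))
}

#' Read a SMILES line file
#'
#' One SMILES per line, optionally followed by a tab and an identifier.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `smiles`.
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[\t ]+")
  data.frame(id = vapply(seq_along(parts), function(i)
               if (length(parts[[i]]) > 1L) parts[[i]][2] else sprintf("cmp%04d", i),
               character(1)),
             smiles = vapply(parts, `[[`, character(1), 1L),
             stringsAsFactors = FALSE)
}

# units map for output headers
.unitSuffix <- c(dG_rxn = "kcal_mol", dG_act = "kcal_mol",
                 dG_act_reverse = "kcal_mol", nu_imag_cm = "cm1",
                 radius_A = "Angstrom", k_TST = "M1s1", k_act = "M1s1",
                 k_D = "M1s1", k_app = "M1s1", k_total = "M1s1",
                 k_global = "M1s1", MW = "g_mol", PSA = "A2", MR = "cm3_mol",
                 LD50 = "mg_kg", fraction = "unitless", pH = "pH",
                 BDE = "kcal_mol", IE = "kcal_mol")

#' Write a stage CSV with unit-suffixed headers
#'
#' Numeric columns are written at 6 significant digits (so re-runs are
#' bit-stable) and known quantity columns carry a units suffix in the
#' header.
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeStageCsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  hit <- names(out) %in% names(.unitSuffix)
  names(out)[hit] <- paste(names(out)[hit], .unitSuffix[names(out)[hit]],
                           sep = "_")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the design workflow end to end
#'
#' Executes the stages in dependency order -- enumerate, describe, score,
#' select, speciate, kinetics, donating-ability map, reaction force --
#' skipping any stage whose inputs are absent, writing one CSV per executed
#' stage plus a JSON summary into `config$outDir`.
#'
#' @param config a [runConfig()] list.
#' @param inputs named list; recognised elements: `scaffold` (a
#'   [ScaffoldSpec-class]), `maxSubstitutions`, `reference` (descriptor
#'   data.frame of the reference set), `external` (data.frame with `id`,
#'   `LD50`, `ames`, `SA` merged onto the cohort), `channels` (channel
#'   data.frame or CSV path), `pka` (named list of
#'   [AcidBaseSystem-class] or CSV path), `bde`/`ie` (map inputs),
#'   `irc` (an [IRCProfile-class] or two-column file path).
#' @return list with the per-stage results (invisibly); `$status` is
#'   `"ok"` or `"nothing to do"`.
#' @export
runPipeline <- function(config = runConfig(), inputs = list()) {
  if (!length(inputs) || all(vapply(inputs, is.null, logical(1)))) {
    message("nothing to do: no inputs supplied")
    return(invisible(list(status = "nothing to do")))
  }
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  res <- list(status = "ok")
  outfile <- function(name) file.path(config$outDir, paste0(name, ".csv"))

  cohort <- NULL
  if (!is.null(inputs$scaffold)) {
    message("stage enumerate")
    derivs <- enumerateDerivatives(inputs$scaffold,
                                   maxSubstitutions = inputs$maxSubstitutions %||% Inf)
    res$derivatives <- derivs
    writeStageCsv(derivs, outfile("derivatives"))
    message("stage describe")
    cohort <- computeDescriptors(derivs$smiles, derivs$id)
    if (!is.null(inputs$external)) {
      keep <- setdiff(names(cohort), c("LD50", "ames", "SA"))
      cohort <- merge(cohort[keep], inputs$external, by = "id", all.x = TRUE,
                      sort = FALSE)
    }
    cohort <- cbind(cohort, checkDruglikeness(cohort))
    res$descriptors <- cohort
    writeStageCsv(cohort, outfile("descriptors"))
  }
  if (!is.null(cohort) && !is.null(inputs$reference)) {
    message("stage score")
    agg <- buildReferenceAggregates(inputs$reference)
    sc <- selectionScore(cohort, agg, config$weights)
    el <- eliminationScore(cohort, agg, config$zThreshold)
    sc$S_E <- el$scores$S_E
    res$scores <- sc
    res$flags <- el$flags
    writeStageCsv(sc, outfile("scores"))
    message("stage select")
    res$candidates <- selectCandidates(sc, config$selectionThresholds)
    writeStageCsv(res$candidates, outfile("candidates"))
  }
  speciation <- NULL
  if (!is.null(inputs$pka)) {
    message("stage speciate")
    systems <- if (is.character(inputs$pka)) readPkaTable(inputs$pka) else inputs$pka
    speciation <- do.call(rbind, lapply(systems, speciationFractions,
                                        pH = config$pH))
    rownames(speciation) <- NULL
    res$speciation <- speciation
    writeStageCsv(speciation, outfile("speciation"))
  }
  if (!is.null(inputs$channels)) {
    message("stage kinetics")
    channels <- if (is.character(inputs$channels)) readChannelTable(inputs$channels)
                else inputs$channels
    report <- assembleRates(channels, solvents = config$solvents,
                            temperature = config$temperature,
                            speciation = speciation,
                            feasibilityFilter = config$feasibilityFilter,
                            radicalRadius_A = config$radicalRadius_A)
    res$rates <- report
    writeStageCsv(channelRates(report), outfile("channel_rates"))
    writeStageCsv(speciesTotals(report), outfile("species_totals"))
    if (nrow(globalRates(report)))
      writeStageCsv(globalRates(report), outfile("global_rates"))
  }
  if (!is.null(inputs$bde) && !is.null(inputs$ie)) {
    message("stage ehdama")
    map <- buildEHDAMA(inputs$bde, inputs$ie)
    res$ehdama <- map
    writeStageCsv(mapPoints(map), outfile("ehdama"))
  }
  if (!is.null(inputs$irc)) {
    message("stage rforce")
    prof <- if (is.character(inputs$irc)) readIrcTable(inputs$irc, config$ircUnits)
            else inputs$irc
    fa <- analyzeReactionForce(prof)
    res$reaction_force <- fa
    writeStageCsv(data.frame(xi = ircCoordinate(prof),
                             energy = ircEnergy(prof),
                             force = reactionForce(fa)),
                  outfile("reaction_force"))
  }

  summary <- list(status = res$status,
                  stages = setdiff(names(res), "status"),
                  pH = config$pH, temperature = config$temperature)
  if (!is.null(res$rates) && nrow(globalRates(res$rates)))
    summary$k_global <- globalRates(res$rates)
  jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [runConfig()]; a `scaffold`
#' block (`core`, `sites`, `library` name/smiles pairs) is turned into a
#' [ScaffoldSpec-class].  Unknown keys are rejected so typos cannot
#' silently fall back to defaults.
#'
#' @param path YAML file.
#' @return list with `config` (a [runConfig()] list) and optionally
#'   `scaffold`.
#' @export
readRunConfigFile <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("temperature", "pH", "ircUnits", "zThreshold",
             "selectionThresholds", "feasibilityFilter", "radicalRadius_A",
             "outDir", "seed", "weights", "scaffold")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  scaffold <- NULL
  if (!is.null(y$scaffold)) {
    lib <- if (length(y$scaffold$library))
      data.frame(name = vapply(y$scaffold$library, `[[`, "", "name"),
                 smiles = vapply(y$scaffold$library, `[[`, "", "smiles"),
                 stringsAsFactors = FALSE)
      else data.frame(name = character(), smiles = character())
    scaffold <- scaffoldSpec(y$scaffold$core, unlist(y$scaffold$sites), lib)
    y$scaffold <- NULL
  }
  if (!is.null(y$weights)) y$weights <- do.call(scoreWeights, as.list(y$weights))
  if (!is.null(y$selectionThresholds))
    y$selectionThresholds <- unlist(y$selectionThresholds)
  list(config = do.call(runConfig, y), scaffold = scaffold)
}
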