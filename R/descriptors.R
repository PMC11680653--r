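#' Compute drug-likeness descriptors for structures
#'
#' Computes the eight ADME descriptors used throughout the design stage:
#' hydrogen-bond donor and acceptor counts (HBD, HBA), molecular weight (MW,
#' g/mol), Crippen-type octanol/water partition coefficient (logP), molar
#' refractivity (MR, cm^3/mol), heavy-atom count (AtX), rotatable-bond count
#' (RB) and Ertl-type topological polar surface area (PSA, A^2).  The values
#' come from OpenBabel's implementations of the standard algorithms.  The
#' externally supplied fields (LD50, Ames mutagenicity, synthetic
#' accessibility) are returned as `NA` columns so the schema is stable.
#'
#' @param smiles character vector of SMILES strings.
#' @param id optional identifiers (defaults to names of `smiles` or
#'   sequential ids).
#' @return data.frame with columns `id`, `smiles`, `HBD`, `HBA`, `MW`,
#'   `logP`, `MR`, `AtX`, `RB`, `PSA`, `LD50`, `ames`, `SA`.
#' @examples
#' \donttest{computeDescriptors("OC(=O)C=Cc1cc(O)c(O)cc1")  # caffeic acid}
#' @export
computeDescriptors <- function(smiles, id = NULL) {
  if (is.null(id)) id <- if (!is.null(names(smiles))) names(smiles) else
    sprintf("cmp%04d", seq_along(smiles))
  stopifnot(length(id) == length(smiles))
  if (!length(smiles))
    return(.emptyDescriptorFrame())
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  tags <- paste0("m", seq_along(smiles))
  writeLines(paste(smiles, tags), infile)
  out <- suppressWarnings(system2("obabel",
    c("-ismi", infile, "-osmi", "--append",
      shQuote("MW HBD HBA1 logP MR TPSA atoms rotors")),
    stdout = TRUE, stderr = FALSE))
  out <- out[nzchar(out)]
  parsed <- strsplit(out, "\t", fixed = TRUE)
  good <- lengths(parsed) == 2L
  fields <- strsplit(vapply(parsed[good], `[[`, character(1), 2L), " +")
  got <- vapply(fields, `[[`, character(1), 1L)
  vals <- t(vapply(fields, function(f) as.numeric(f[-1]), numeric(8)))
  idx <- match(tags, got)
  if (anyNA(idx))
    stop("structure error: unparsable SMILES: ",
         paste(smiles[is.na(idx)], collapse = ", "))
  vals <- vals[idx, , drop = FALSE]
  data.frame(id = id, smiles = unname(smiles),
             HBD = as.integer(vals[, 2]), HBA = as.integer(vals[, 3]),
             MW = vals[, 1], logP = vals[, 4], MR = vals[, 5],
             AtX = as.integer(vals[, 7]), RB = as.integer(vals[, 8]),
             PSA = vals[, 6],
             LD50 = NA_real_, ames = NA_real_, SA = NA_real_,
             stringsAsFactors = FALSE)
}

.emptyDescriptorFrame <- function() {
  data.frame(id = character(), smiles = character(), HBD = integer(),
             HBA = integer(), MW = numeric(), logP = numeric(), MR = numeric(),
             AtX = integer(), RB = integer(), PSA = numeric(),
             LD50 = numeric(), ames = numeric(), SA = numeric(),
             stringsAsFactors = FALSE)
}

# property -> columns needed by each rule
.ruleSpec <- list(
  lipinski = list(MW = c(-Inf, 500), logP = c(-Inf, 5), HBD = c(-Inf, 5),
                  HBA = c(-Inf, 10)),
  ghose    = list(MW = c(160, 480), logP = c(-0.4, 5.6), MR = c(40, 130),
                  AtX = c(20, 70)),
  veber    = list(RB = c(-Inf, 10), PSA = c(-Inf, 140)))

#' Check compliance with drug-likeness rules
#'
#' Evaluates the Lipinski rule of five (MW <= 500, logP <= 5, HBD <= 5,
#' HBA <= 10), the Ghose rule (160 <= MW <= 480, -0.4 <= logP <= 5.6,
#' 40 <= MR <= 130, 20 <= AtX <= 70) and the Veber criteria (RB <= 10,
#' PSA <= 140 A^2).  All bounds are inclusive: a compound sitting exactly on
#' a boundary passes.  Each rule's aggregate pass is the conjunction of its
#' per-criterion checks.
#'
#' @param descriptors data.frame as returned by [computeDescriptors()] (or
#'   any frame with the required columns).
#' @return data.frame with one logical column per criterion
#'   (e.g. `lipinski_MW`) plus `lipinski_pass`, `ghose_pass`, `veber_pass`.
#' @examples
#' d <- data.frame(MW = 180.16, logP = 1.2, HBD = 3, HBA = 4, MR = 47.2,
#'                 AtX = 13, RB = 2, PSA = 77.8)
#' checkDruglikeness(d)
#' @export
checkDruglikeness <- function(descriptors) {
  need <- unique(unlist(lapply(.ruleSpec, names)))
  missing <- setdiff(need, names(descriptors))
  if (length(missing))
    stop("incomplete descriptor record: missing field(s) ",
         paste(missing, collapse = ", "))
  for (col in need)
    if (anyNA(descriptors[[col]]))
      stop("incomplete descriptor record: NA in field ", col)
  out <- data.frame(row.names = seq_len(nrow(descriptors)))
  for (rule in names(.ruleSpec)) {
    crits <- .ruleSpec[[rule]]
    ok <- rep(TRUE, nrow(descriptors))
    for (prop in names(crits)) {
      b <- crits[[prop]]
      pass <- descriptors[[prop]] >= b[1] & descriptors[[prop]] <= b[2]
      out[[paste(rule, prop, sep = "_")]] <- pass
      ok <- ok & pass
    }
    out[[paste0(rule, "_pass")]] <- ok
  }
  out
}
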