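#' Construct a substitutable scaffold
#'
#' @param core SMILES template with one `({Rk})` token per substitution site
#'   (for a site at a ring-closure atom the braces token may also appear
#'   without parentheses, e.g. `c1{R3}`).
#' @param siteLabels ordered character vector of unique site labels.
#' @param fragments data.frame with columns `name`, `smiles`; every fragment
#'   SMILES must start with the dummy-atom attachment point `[*]`.  Hydrogen
#'   is implicit at every site and must not be listed.
#' @return A [ScaffoldSpec-class] object.
#' @examples
#' scaffoldSpec("c1ccc({R1})cc1{R2}", c("R1", "R2"),
#'              data.frame(name = "F", smiles = "[*]F"))
#' @export
scaffoldSpec <- function(core, siteLabels, fragments = data.frame(name = character(),
                                                                  smiles = character())) {
  fragments <- as.data.frame(fragments, stringsAsFactors = FALSE)
  if (nrow(fragments) && !all(startsWith(fragments$smiles, "[*]")))
    stop("fragment SMILES must begin with the [*] attachment point: ",
         paste(fragments$name[!startsWith(fragments$smiles, "[*]")], collapse = ", "))
  obj <- new("ScaffoldSpec", core = core, siteLabels = siteLabels,
             fragments = fragments)
  # the parent structure must itself parse
  parent <- .spliceScaffold(obj, setNames(rep("H", length(siteLabels)), siteLabels))
  ok <- tryCatch({ canonicalSmiles(parent); TRUE }, error = function(e) FALSE)
  if (!ok) stop("core template does not yield a parsable parent structure: ", parent)
  obj
}

#' The caffeic-acid scaffold with its substituent library
#'
#' The bundled design scaffold: caffeic acid with five inequivalent
#' substitutable positions (three free aromatic ring positions and the two
#' vinylic positions of the acrylic-acid arm) and the seven-group substituent
#' library -OH, -SH, -OCH3, -COOCH3, -F, -CF3 and -N(CH3)(C2H5).
#'
#' @return A [ScaffoldSpec-class] with sites R1..R5.
#' @examples
#' caffeicAcidScaffold()
#' @export
caffeicAcidScaffold <- function() {
  scaffoldSpec(
    core = "OC(=O)C({R4})=C({R5})c1c({R1})c(O)c(O)c({R2})c1{R3}",
    siteLabels = paste0("R", 1:5),
    fragments = data.frame(
      name   = c("OH", "SH", "OCH3", "COOCH3", "F", "CF3", "N(CH3)(C2H5)"),
      smiles = c("[*]O", "[*]S", "[*]OC", "[*]C(=O)OC", "[*]F",
                 "[*]C(F)(F)F", "[*]N(C)CC"),
      stringsAsFactors = FALSE))
}

# Splice substituents into the core template.  pattern is a named character
# vector site label -> substituent name ("H" for unsubstituted).
.spliceScaffold <- function(scaffold, pattern) {
  smi <- scaffold@core
  frags <- scaffold@fragments
  for (lab in scaffold@siteLabels) {
    sub <- pattern[[lab]]
    if (identical(sub, "H")) {
      smi <- gsub(paste0("({", lab, "})"), "", smi, fixed = TRUE)
      smi <- gsub(paste0("{", lab, "}"), "", smi, fixed = TRUE)
    } else {
      frag <- frags$smiles[match(sub, frags$name)]
      if (is.na(frag)) stop("unknown substituent name: ", sub)
      body <- sub("[*]", "", frag, fixed = TRUE)
      smi <- gsub(paste0("{", lab, "}"), body, smi, fixed = TRUE)
    }
  }
  smi
}

#' Canonicalise SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES in one batched call; used
#' for structure-based deduplication.  Unparsable inputs raise an error that
#' names the offending string.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, same length and names.
#' @examples
#' \donttest{canonicalSmiles(c("OCC", "C(C)O"))  # both ethanol}
#' @export
canonicalSmiles <- function(smiles) {
  if (!length(smiles)) return(character())
  ids <- paste0("m", seq_along(smiles))
  txt <- paste0(paste(smiles, ids), "\n", collapse = "")
  out <- suppressWarnings(tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", txt),
    error = function(e) ""))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) trimws(p[min(2L, length(p))]), character(1))
  can <- vapply(parts, `[[`, character(1), 1L)
  res <- can[match(ids, got)]
  if (anyNA(res)) {
    bad <- smiles[is.na(res)]
    stop("unparsable SMILES: ", paste(bad, collapse = ", "))
  }
  names(res) <- names(smiles)
  res
}

#' Enumerate scaffold derivatives
#'
#' Generates every distinct assignment of library substituents (or hydrogen)
#' to the scaffold's sites with at most `maxSubstitutions` non-hydrogen
#' entries.  Patterns are produced in a deterministic lexicographic order
#' (sites in scaffold order; at each site hydrogen first, then the library in
#' its stored order) and deduplicated on canonical structure, keeping the
#' first pattern that realises each structure.
#'
#' @param scaffold a [ScaffoldSpec-class].
#' @param maxSubstitutions maximum number of non-hydrogen sites (default
#'   `Inf`, i.e. unlimited).
#' @param patternFilter optional predicate `function(pattern)` receiving the
#'   named character pattern vector; patterns for which it returns `FALSE`
#'   are dropped before structures are built.  This is the hook for any
#'   cohort-reduction policy.
#' @param canonicalize logical; if `TRUE` (default) structures are
#'   canonicalised (and deduplicated on the canonical form), otherwise the
#'   raw spliced SMILES is used as the structure key.  Turning it off is
#'   useful for counting raw pattern spaces.
#' @return data.frame with columns `id`, one column per site label, and
#'   `smiles`; one row per distinct derivative.
#' @examples
#' sc <- scaffoldSpec("c1ccc({R1})cc1{R2}", c("R1", "R2"),
#'                    data.frame(name = "F", smiles = "[*]F"))
#' enumerateDerivatives(sc)  # H/H, H/F, F/H, F/F
#' @export
enumerateDerivatives <- function(scaffold, maxSubstitutions = Inf,
                                 patternFilter = NULL, canonicalize = TRUE) {
  stopifnot(is(scaffold, "ScaffoldSpec"))
  validObject(scaffold)
  if (maxSubstitutions < 0) stop("maxSubstitutions must be >= 0")
  sites <- scaffold@siteLabels
  options <- c("H", scaffold@fragments$name)
  # odometer order: first site most significant, hydrogen before library
  grids <- rev(expand.grid(rev(setNames(rep(list(options), length(sites)), sites)),
                           stringsAsFactors = FALSE))
  nsub <- rowSums(grids != "H")
  grids <- grids[nsub <= maxSubstitutions, , drop = FALSE]
  if (!is.null(patternFilter)) {
    keep <- vapply(seq_len(nrow(grids)),
                   function(i) isTRUE(patternFilter(unlist(grids[i, , drop = FALSE]))),
                   logical(1))
    grids <- grids[keep, , drop = FALSE]
  }
  if (!nrow(grids))
    return(cbind(data.frame(id = character()), grids, data.frame(smiles = character())))
  raw <- vapply(seq_len(nrow(grids)),
                function(i) .spliceScaffold(scaffold, unlist(grids[i, , drop = FALSE])),
                character(1))
  structure_key <- if (canonicalize) canonicalSmiles(raw) else raw
  keep <- !duplicated(structure_key)
  out <- grids[keep, , drop = FALSE]
  out <- cbind(data.frame(id = sprintf("drv%05d", seq_len(sum(keep))),
                          stringsAsFactors = FALSE),
               out,
               data.frame(smiles = unname(structure_key[keep]),
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
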