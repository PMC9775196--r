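## Thin layer over Open Babel (via ChemmineOB). Everything downstream —
## standardization, alert matching — funnels through these helpers so the
## aromaticity/valence model is applied consistently in one place.

#' Canonicalize a SMILES string with Open Babel
#'
#' Converts a SMILES string to Open Babel's canonical form. Multi-fragment
#' inputs are preserved (fragments stay dot-separated). Stereochemistry
#' present in the input is retained; use [standardize_structure()] for the
#' full standardization pipeline which removes it.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` where a string could
#'   not be parsed.
#' @examples
#' canonical_smiles(c("OCC", "CCO"))  # identical output
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = s)),
      error = function(e) ""
    )
    out <- sub("[ \t].*$", "", trimws(out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Check that SMARTS patterns compile
#'
#' @param patterns character vector of SMARTS strings.
#' @return logical vector, `TRUE` where the pattern parses under Open Babel.
#' @export
smarts_valid <- function(patterns) {
  vapply(patterns, function(p) {
    if (is.na(p) || !nzchar(p)) return(FALSE)
    ok <- tryCatch({
      suppressWarnings(count_smarts_matches("C", p))
      TRUE
    }, error = function(e) FALSE)
    ok
  }, logical(1), USE.NAMES = FALSE)
}

#' Count unique embeddings of SMARTS patterns in one molecule
#'
#' The molecule is parsed once and every pattern evaluated against it.
#' Counts are of unique atom mappings (symmetry-duplicated embeddings
#' collapse to one).
#'
#' @param smiles a single SMILES string.
#' @param patterns character vector of SMARTS.
#' @return integer vector of match counts, one per pattern. Unparseable
#'   SMILES give an error.
#' @export
count_smarts_matches <- function(smiles, patterns) {
  stopifnot(length(smiles) == 1L)
  res <- ChemmineOB::forEachMol("SMILES", smiles, function(mol) {
    vapply(patterns, function(p)
      as.integer(ChemmineOB::smartsSearch_OB(list(mol), p)), integer(1))
  })
  out <- res[[1]]
  names(out) <- NULL
  out
}

## First embedding of `pattern` in `smiles`, as 1-based atom indices in Open
## Babel's atom order. Uses the low-level OBSmartsPattern API; returns
## integer(0) if there is no match or the API is unavailable.
first_match_atoms <- function(smiles, pattern) {
  ns <- getNamespace("ChemmineOB")
  need <- c("OBSmartsPattern", "OBSmartsPattern_Init",
            "OBSmartsPattern_Match", "OBSmartsPattern_GetUMapList")
  if (!all(vapply(need, exists, logical(1), envir = ns))) return(integer(0))
  sp <- ns$OBSmartsPattern()
  on.exit(ns$delete_OBSmartsPattern(sp), add = TRUE)
  if (!ns$OBSmartsPattern_Init(sp, pattern)) return(integer(0))
  res <- ChemmineOB::forEachMol("SMILES", smiles, function(mol) {
    ns$OBSmartsPattern_Match(sp, mol)
    ns$OBSmartsPattern_GetUMapList(sp)
  })
  maps <- res[[1]]
  if (length(maps) == 0) return(integer(0))
  as.integer(maps[[1]])
}

## ---- SMILES fragment utilities (text level) -------------------------------
## Salt stripping needs per-fragment heavy-atom counts. Dot-disconnection is
## purely lexical in SMILES, so fragments can be split on "." outside of any
## context; atom counting walks the string token by token (bracket atoms,
## two-letter organic-subset halogens, aromatic subset).

split_fragments <- function(smiles) strsplit(smiles, ".", fixed = TRUE)[[1]]

## Count heavy (non-H) atoms and carbon atoms in one SMILES fragment.
## Bracket atoms count as written (explicit [H] counts zero); organic-subset
## symbols are tokenized longest-first so "Cl"/"Br" are not misread as C/B.
fragment_atom_counts <- function(frag) {
  heavy <- 0L; carbon <- 0L
  i <- 1L; n <- nchar(frag)
  while (i <= n) {
    ch <- substr(frag, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(frag, i, n), fixed = TRUE)
      if (j < 0) stop("unbalanced bracket in SMILES fragment: ", frag)
      body <- substr(frag, i + 1L, i + j - 2L)
      elem <- regmatches(body, regexpr("[A-Za-z][a-z]?", body))
      if (length(elem) == 1L && !identical(elem, "H")) {
        heavy <- heavy + 1L
        if (elem %in% c("C", "c")) carbon <- carbon + 1L
      }
      i <- i + j
    } else {
      two <- substr(frag, i, min(i + 1L, n))
      if (two %in% c("Cl", "Br")) {
        heavy <- heavy + 1L
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                           "b", "c", "n", "o", "p", "s")) {
        heavy <- heavy + 1L
        if (ch %in% c("C", "c")) carbon <- carbon + 1L
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  c(heavy = heavy, carbon = carbon)
}

fragment_has_carbon <- function(frag) fragment_atom_counts(frag)[["carbon"]] > 0L

## Remove stereochemical marks from a SMILES string. "@" (tetrahedral) and
## "/", "\\" (double-bond configuration) occur in SMILES only as stereo
## descriptors, so lexical deletion is exact.
strip_stereo_smiles <- function(smiles) gsub("[@/\\\\]", "", smiles)

## Open Babel molecular weight, for salt-stripping tie-breaks.
molecular_weight <- function(smiles) {
  res <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol(
      "SMILES", smiles, function(mol) ChemmineOB::prop_OB(mol))[[1]]),
    error = function(e) NULL
  )
  if (is.null(res) || is.null(res$MW)) return(NA_real_)
  as.numeric(res$MW)
}
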