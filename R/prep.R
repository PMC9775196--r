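## Structure standardization: canonicalize, strip salts, delete
## stereochemistry, remove duplicates/inorganics/mixtures, with every
## rejected record accounted for in a rejection log.

REJECT_REASONS <- c("unparseable", "inorganic", "mixture",
                    "undefined_structure", "duplicate")

#' Standardize one raw structure record
#'
#' Applies the preprocessing pipeline to a single SMILES: parse, delete
#' stereochemistry, strip salt/counterion fragments (keeping the
#' carbon-containing fragment with the most heavy atoms; ties broken by
#' molecular weight, then lexicographically smallest canonical SMILES), and
#' canonicalize with Open Babel. Records with no carbon-containing fragment
#' are rejected as `inorganic`; records where two or more organic fragments
#' remain and the largest holds no more than `mixture_threshold` of their
#' heavy atoms are rejected as `mixture`; records flagged polymeric are
#' rejected as `undefined_structure` (polymericity is not derivable from a
#' SMILES line, so it must be supplied).
#'
#' @param smiles a single SMILES string.
#' @param record_id identifier carried through to the output.
#' @param source inventory label carried through.
#' @param polymer_flag logical; `TRUE` marks the record as polymeric or
#'   otherwise lacking a defined structure.
#' @param mixture_threshold heavy-atom fraction the dominant organic
#'   fragment must exceed for salt stripping to apply instead of mixture
#'   rejection (default 0.7).
#' @return a list of class `standardized_compound` with elements
#'   `record_id`, `parent_smiles`, `transformations` (subset of
#'   `salt_stripped`, `stereo_removed`, `canonicalized`),
#'   `n_fragments_removed`, `source` — or of class `rejected_record` with
#'   elements `record_id`, `reason`, `source`.
#' @examples
#' standardize_structure("CCO.Cl", "r1")       # salt stripped to CCO
#' standardize_structure("[Na+].[Cl-]", "r2")  # rejected: inorganic
#' @export
standardize_structure <- function(smiles, record_id = smiles,
                                  source = NA_character_,
                                  polymer_flag = FALSE,
                                  mixture_threshold = 0.7) {
  reject <- function(reason) structure(
    list(record_id = record_id, reason = reason, source = source),
    class = "rejected_record")

  if (isTRUE(polymer_flag)) return(reject("undefined_structure"))
  if (is.na(smiles) || !nzchar(trimws(smiles))) return(reject("unparseable"))
  smiles <- trimws(smiles)

  transformations <- character(0)
  destereo <- strip_stereo_smiles(smiles)
  if (!identical(destereo, smiles)) transformations <- c(transformations, "stereo_removed")

  canon_all <- canonical_smiles(destereo)
  if (is.na(canon_all)) return(reject("unparseable"))

  frags <- split_fragments(canon_all)
  organic <- frags[vapply(frags, fragment_has_carbon, logical(1))]
  if (length(organic) == 0L) return(reject("inorganic"))

  parent <- organic[[1L]]
  if (length(frags) > 1L) {
    heavy <- vapply(organic, function(f) fragment_atom_counts(f)[["heavy"]], integer(1))
    if (length(organic) >= 2L &&
        max(heavy) <= mixture_threshold * sum(heavy)) return(reject("mixture"))
    top <- organic[heavy == max(heavy)]
    if (length(top) > 1L) {
      mw <- vapply(top, molecular_weight, numeric(1))
      mw[is.na(mw)] <- -Inf
      top <- top[mw == max(mw)]
      top <- sort(top)
    }
    parent <- top[[1L]]
    transformations <- c(transformations, "salt_stripped")
  }

  parent_canon <- canonical_smiles(parent)
  if (is.na(parent_canon)) return(reject("unparseable"))
  transformations <- c(transformations, "canonicalized")

  structure(list(
    record_id = record_id,
    parent_smiles = parent_canon,
    transformations = transformations,
    n_fragments_removed = length(frags) - 1L,
    source = source
  ), class = "standardized_compound")
}

#' Preprocess a chemical inventory
#'
#' Vectorized standardization with duplicate removal: each record passes
#' through [standardize_structure()]; records whose parent structure has
#' already been produced by an earlier record (after canonicalization, so
#' spelling variants of one molecule collapse) are rejected as `duplicate`.
#' Every input record appears exactly once across the standardized set and
#' the rejection log.
#'
#' @param records data.frame with columns `record_id`, `smiles` and
#'   optionally `source` and logical `polymer_flag`.
#' @param mixture_threshold passed to [standardize_structure()].
#' @return list of class `preprocessed_inventory` with elements
#'   `compounds` (data.frame: `record_id`, `parent_smiles`,
#'   `transformations` list-column, `n_fragments_removed`, `source`) and
#'   `rejections` (data.frame: `record_id`, `reason`, `source`).
#' @examples
#' inv <- data.frame(record_id = c("a", "b"), smiles = c("CCO", "OCC"))
#' preprocess_inventory(inv)  # one compound, one duplicate rejection
#' @export
preprocess_inventory <- function(records, mixture_threshold = 0.7) {
  stopifnot(is.data.frame(records),
            all(c("record_id", "smiles") %in% names(records)))
  if (anyDuplicated(records$record_id))
    stop("record_id values must be unique within an inventory")
  n <- nrow(records)
  src <- if ("source" %in% names(records)) as.character(records$source) else rep(NA_character_, n)
  pf <- if ("polymer_flag" %in% names(records)) records$polymer_flag else rep(FALSE, n)

  comp_rows <- list(); rej_rows <- list()
  seen <- character(0)
  for (i in seq_len(n)) {
    res <- standardize_structure(as.character(records$smiles[i]),
                                 record_id = as.character(records$record_id[i]),
                                 source = src[i], polymer_flag = isTRUE(pf[i]),
                                 mixture_threshold = mixture_threshold)
    if (inherits(res, "rejected_record")) {
      rej_rows[[length(rej_rows) + 1L]] <- res
    } else if (res$parent_smiles %in% seen) {
      rej_rows[[length(rej_rows) + 1L]] <- structure(
        list(record_id = res$record_id, reason = "duplicate", source = src[i]),
        class = "rejected_record")
    } else {
      seen <- c(seen, res$parent_smiles)
      comp_rows[[length(comp_rows) + 1L]] <- res
    }
  }

  compounds <- data.frame(
    record_id = vapply(comp_rows, `[[`, character(1), "record_id"),
    parent_smiles = vapply(comp_rows, `[[`, character(1), "parent_smiles"),
    n_fragments_removed = vapply(comp_rows, `[[`, integer(1), "n_fragments_removed"),
    source = vapply(comp_rows, `[[`, character(1), "source"),
    stringsAsFactors = FALSE
  )
  compounds$transformations <- lapply(comp_rows, `[[`, "transformations")
  rejections <- data.frame(
    record_id = vapply(rej_rows, `[[`, character(1), "record_id"),
    reason = vapply(rej_rows, `[[`, character(1), "reason"),
    source = vapply(rej_rows, `[[`, character(1), "source"),
    stringsAsFactors = FALSE
  )
  structure(list(compounds = compounds, rejections = rejections),
            class = "preprocessed_inventory")
}

#' @export
print.preprocessed_inventory <- function(x, ...) {
  cat(sprintf("Preprocessed inventory: %d standardized, %d rejected\n",
              nrow(x$compounds), nrow(x$rejections)))
  if (nrow(x$rejections))
    print(table(reason = x$rejections$reason))
  invisible(x)
}

#' @export
print.standardized_compound <- function(x, ...) {
  cat(sprintf("<%s> %s  [%s]\n", x$record_id, x$parent_smiles,
              paste(x$transformations, collapse = ", ")))
  invisible(x)
}

#' @export
print.rejected_record <- function(x, ...) {
  cat(sprintf("<%s> rejected: %s\n", x$record_id, x$reason))
  invisible(x)
}

## ---- inventory readers ----------------------------------------------------

#' Read a chemical inventory file
#'
#' Reads `.smi` (one SMILES per line, optional whitespace-delimited id),
#' `.csv` (configurable SMILES/id columns) or `.sdf` (title line as id,
#' structure converted to SMILES via Open Babel) into the raw-record
#' data.frame expected by [preprocess_inventory()].
#'
#' @param path input file.
#' @param format one of `"auto"` (by extension), `"smi"`, `"csv"`, `"sdf"`.
#' @param smiles_col,id_col CSV column names (defaults `"smiles"`; id falls
#'   back to row numbers).
#' @param source inventory label stamped on every record; defaults to the
#'   file name.
#' @return data.frame with columns `record_id`, `smiles`, `source`.
#' @export
read_inventory <- function(path, format = c("auto", "smi", "csv", "sdf"),
                           smiles_col = "smiles", id_col = NULL,
                           source = basename(path)) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smi", csv = "csv", sdf = "sdf",
                     stop("cannot infer inventory format from extension: ", ext))
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "[ \t]+")
    smiles <- vapply(parts, `[[`, character(1), 1L)
    ids <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1L) parts[[i]][2L] else sprintf("rec%04d", i),
      character(1))
  } else if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!smiles_col %in% names(df))
      stop("CSV lacks SMILES column '", smiles_col, "'")
    smiles <- as.character(df[[smiles_col]])
    ids <- if (!is.null(id_col)) {
      if (!id_col %in% names(df)) stop("CSV lacks id column '", id_col, "'")
      as.character(df[[id_col]])
    } else sprintf("rec%04d", seq_along(smiles))
  } else {
    if (!requireNamespace("ChemmineR", quietly = TRUE))
      stop("reading SDF requires the ChemmineR package")
    sdf <- ChemmineR::read.SDFset(path)
    smiles <- as.character(ChemmineR::sdf2smiles(sdf))
    ids <- vapply(seq_along(smiles), function(i) {
      ttl <- ChemmineR::sdfid(sdf[i])
      if (length(ttl) && nzchar(ttl)) as.character(ttl) else sprintf("rec%04d", i)
    }, character(1))
  }
  data.frame(record_id = ids, smiles = smiles, source = source,
             stringsAsFactors = FALSE)
}
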