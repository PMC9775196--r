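## Harmonization of external classification-scheme outputs (Verhaar,
## Russom, MechoA, ...) onto the three broad domains, and domain-level
## concordance between schemes.

HARMONIZED_LEVELS <- c("narcotic", "reactive", "specific",
                       "unclassified_or_out_of_domain")

#' Default interscheme domain mapping
#'
#' Returns the mapping table shipped with the package, covering the class
#' labels of the Verhaar, Russom and MechoA schemes. The anchor rows are
#' Verhaar class 3 -> reactive, Russom class 6 -> specific and MechoA 1.3
#' -> narcotic; the remaining rows extend those anchors by each scheme's
#' own class semantics (Verhaar 1/2 narcosis classes, Verhaar 4 specific,
#' Verhaar 5 unclassifiable; Russom narcosis and electrophile classes;
#' MechoA top-level families). Supply your own CSV via
#' [read_domain_mapping()] to override.
#'
#' @return data.frame with columns `scheme`, `native_class`, `harmonized`.
#' @export
default_domain_mapping <- function() {
  path <- system.file("extdata", "scheme_mapping.csv", package = "aquaprof")
  read_domain_mapping(path)
}

#' Read an interscheme domain mapping CSV
#'
#' @param path CSV with columns `scheme`, `native_class`, `harmonized`.
#' @return validated mapping data.frame.
#' @export
read_domain_mapping <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", comment.char = "#")
  need <- c("scheme", "native_class", "harmonized")
  if (!all(need %in% names(m)))
    stop("mapping CSV must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(m$harmonized), HARMONIZED_LEVELS)
  if (length(bad))
    stop("mapping contains unknown harmonized label(s): ",
         paste(bad, collapse = ", "))
  key <- paste(m$scheme, m$native_class, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (scheme, native_class) pair(s) in mapping")
  m[need]
}

#' Harmonize an external scheme's assignments to the broad domains
#'
#' Replaces each native class label with its harmonized domain
#' (`narcotic`, `reactive`, `specific` or
#' `unclassified_or_out_of_domain`). Rows whose label has no mapping entry
#' are kept, flagged `unmapped = TRUE`, and collected in the `unmapped`
#' attribute — never silently dropped. Multiple rows per record (schemes
#' granting several assignments) are preserved. Labels already drawn from
#' the harmonized vocabulary pass through unchanged, so harmonization is
#' idempotent.
#'
#' @param external data.frame with columns `record_id` and `native_class`
#'   (one row per assignment), plus a `scheme` column or the `scheme`
#'   argument.
#' @param mapping mapping data.frame from [read_domain_mapping()] or
#'   [default_domain_mapping()].
#' @param scheme scheme name used when `external` lacks a `scheme` column.
#' @param in_domain optional logical vector (or column name in `external`)
#'   marking whether each record sits inside the scheme's applicability
#'   domain, for schemes such as Russom that classify by default; carried
#'   through as an `in_domain` column when present.
#' @return data.frame of class `harmonized_table` with columns `record_id`,
#'   `scheme`, `native_class`, `harmonized`, `unmapped` (and `in_domain` if
#'   supplied); attribute `unmapped` holds the unmapped subset.
#' @examples
#' ext <- data.frame(record_id = "c1", native_class = "3")
#' harmonize_assignments(ext, default_domain_mapping(), scheme = "verhaar")
#' @export
harmonize_assignments <- function(external, mapping, scheme = NULL,
                                  in_domain = NULL) {
  stopifnot(is.data.frame(external))
  if (!"record_id" %in% names(external))
    stop("external table lacks required column 'record_id'")
  if (!"native_class" %in% names(external))
    stop("external table lacks required column 'native_class'")
  if (is.null(scheme)) {
    if (!"scheme" %in% names(external))
      stop("supply a 'scheme' column or the scheme= argument")
    schemes <- as.character(external$scheme)
  } else schemes <- rep(scheme, nrow(external))

  native <- as.character(external$native_class)
  key <- paste(schemes, native, sep = "\r")
  mkey <- paste(mapping$scheme, mapping$native_class, sep = "\r")
  harmonized <- mapping$harmonized[match(key, mkey)]
  ## identity on already-harmonized labels
  pre <- native %in% HARMONIZED_LEVELS & is.na(harmonized)
  harmonized[pre] <- native[pre]
  unmapped <- is.na(harmonized)

  out <- data.frame(record_id = as.character(external$record_id),
                    scheme = schemes, native_class = native,
                    harmonized = harmonized, unmapped = unmapped,
                    stringsAsFactors = FALSE)
  if (!is.null(in_domain)) {
    out$in_domain <- if (is.character(in_domain) && length(in_domain) == 1L)
      as.logical(external[[in_domain]]) else as.logical(in_domain)
  }
  attr(out, "unmapped") <- out[out$unmapped, , drop = FALSE]
  class(out) <- c("harmonized_table", "data.frame")
  out
}

#' Domain-level concordance between two harmonized tables
#'
#' Joins two harmonized tables on the intersection of their record ids and
#' cross-tabulates harmonized labels into a 4x4 contingency table.
#' Multi-assignment records contribute one unit per (label in a, label in
#' b) pair. Raw coverage per scheme — records carrying at least one label
#' other than `unclassified_or_out_of_domain` — is computed over the
#' shared records.
#'
#' @param a,b `harmonized_table` objects.
#' @return list of class `concordance_table`: `contingency` (4x4 matrix,
#'   rows = a, cols = b), `n_records` (shared), `n_only_a`, `n_only_b`
#'   (records outside the intersection), `coverage` (named count of
#'   in-coverage records per scheme over the shared set).
#' @export
concordance <- function(a, b) {
  stopifnot(inherits(a, "harmonized_table"), inherits(b, "harmonized_table"))
  ids <- intersect(unique(a$record_id), unique(b$record_id))
  if (!length(ids)) stop("the two tables share no record ids")
  lab <- function(tab, id) {
    v <- unique(tab$harmonized[tab$record_id == id & !tab$unmapped])
    v[!is.na(v)]
  }
  cont <- matrix(0L, 4L, 4L, dimnames = list(HARMONIZED_LEVELS, HARMONIZED_LEVELS))
  cov_a <- 0L; cov_b <- 0L
  for (id in ids) {
    la <- lab(a, id); lb <- lab(b, id)
    if (any(la != "unclassified_or_out_of_domain")) cov_a <- cov_a + 1L
    if (any(lb != "unclassified_or_out_of_domain")) cov_b <- cov_b + 1L
    for (x in la) for (y in lb) cont[x, y] <- cont[x, y] + 1L
  }
  scheme_a <- if (length(unique(a$scheme)) == 1L) a$scheme[1L] else "a"
  scheme_b <- if (length(unique(b$scheme)) == 1L) b$scheme[1L] else "b"
  structure(list(
    contingency = cont,
    n_records = length(ids),
    n_only_a = length(setdiff(unique(a$record_id), ids)),
    n_only_b = length(setdiff(unique(b$record_id), ids)),
    coverage = stats::setNames(c(cov_a, cov_b), c(scheme_a, scheme_b))
  ), class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("Concordance over %d shared records (%d / %d unshared)\n",
              x$n_records, x$n_only_a, x$n_only_b))
  print(x$contingency)
  cat("Raw coverage: ",
      paste(sprintf("%s: %d", names(x$coverage), x$coverage), collapse = ", "), "\n")
  invisible(x)
}
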