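## Tiered alert knowledge base: three Tier 1 domains (narcosis, reactive,
## specific), mechanistic groups at Tier 2, mechanistic subgroups at Tier 3,
## molecular initiating events (MIEs) beneath subgroups, and structural
## alerts (ordered SMARTS conjunctions with optional exclusion vetoes)
## beneath MIEs.

DOMAIN_NAMES <- c("1" = "narcosis", "2" = "reactive", "3" = "specific")

#' Load an alert knowledge base
#'
#' Reads a hierarchical alert knowledge base from YAML (canonical) or JSON
#' (accepted; chosen by file extension). The file must carry top-level keys
#' `metadata`, `domains`, `groups`, `subgroups`, `mies` and `alerts`; the
#' layout is documented by the schema file shipped at
#' `system.file("extdata", "kb-schema.json", package = "aquaprof")`.
#'
#' Structural integrity (unique ids, resolvable parent references, id-prefix
#' consistency, compilable SMARTS) is enforced at load time; the
#' example-based checks of [validate_kb()] are not run here, so loading a
#' large KB stays fast.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` KB file.
#' @return an object of class `alert_kb`: a list with data.frame elements
#'   `domains`, `groups`, `subgroups`, `mies`, `alerts` (list-columns for
#'   SMARTS sequences, exclusions, taxa and examples) and a `metadata` list.
#' @seealso [validate_kb()], [kb_summary()], [core_kb()]
#' @examples
#' kb <- core_kb()
#' kb
#' @export
load_kb <- function(path) {
  if (!file.exists(path)) stop("KB file does not exist: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop("KB parse error in ", path, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  build_kb(raw, source_path = path)
}

## Assemble and structurally validate an alert_kb from parsed list data.
build_kb <- function(raw, source_path = NA_character_) {
  for (key in c("metadata", "domains", "groups", "subgroups", "mies", "alerts")) {
    if (is.null(raw[[key]]))
      stop("KB is missing required top-level key '", key, "'")
  }
  getf <- function(rec, field, default = NA_character_) {
    v <- rec[[field]]
    if (is.null(v)) default else v
  }
  chr_list <- function(recs, field) {
    lapply(recs, function(r) {
      v <- r[[field]]
      if (is.null(v)) character(0) else as.character(unlist(v))
    })
  }

  domains <- data.frame(
    id = vapply(raw$domains, function(d) as.integer(getf(d, "id", NA)), integer(1)),
    name = vapply(raw$domains, function(d) as.character(getf(d, "name")), character(1)),
    stringsAsFactors = FALSE
  )
  groups <- data.frame(
    id = vapply(raw$groups, function(g) as.character(getf(g, "id")), character(1)),
    name = vapply(raw$groups, function(g) as.character(getf(g, "name")), character(1)),
    domain_id = vapply(raw$groups, function(g) as.integer(getf(g, "domain_id", NA)), integer(1)),
    stringsAsFactors = FALSE
  )
  subgroups <- data.frame(
    id = vapply(raw$subgroups, function(s) as.character(getf(s, "id")), character(1)),
    name = vapply(raw$subgroups, function(s) as.character(getf(s, "name")), character(1)),
    group_id = vapply(raw$subgroups, function(s) as.character(getf(s, "group_id")), character(1)),
    stringsAsFactors = FALSE
  )
  mies <- data.frame(
    id = vapply(raw$mies, function(m) as.character(getf(m, "id")), character(1)),
    name = vapply(raw$mies, function(m) as.character(getf(m, "name")), character(1)),
    subgroup_id = vapply(raw$mies, function(m) as.character(getf(m, "subgroup_id")), character(1)),
    description = vapply(raw$mies, function(m) as.character(getf(m, "description", "")), character(1)),
    stringsAsFactors = FALSE
  )
  alerts <- data.frame(
    id = vapply(raw$alerts, function(a) as.character(getf(a, "id")), character(1)),
    name = vapply(raw$alerts, function(a) as.character(getf(a, "name")), character(1)),
    mie_id = vapply(raw$alerts, function(a) as.character(getf(a, "mie_id")), character(1)),
    notes = vapply(raw$alerts, function(a) as.character(getf(a, "notes", "")), character(1)),
    stringsAsFactors = FALSE
  )
  alerts$smarts_sequence <- chr_list(raw$alerts, "smarts_sequence")
  alerts$exclusions <- chr_list(raw$alerts, "exclusions")
  alerts$taxa <- chr_list(raw$alerts, "taxa")
  alerts$positive_examples <- chr_list(raw$alerts, "positive_examples")
  alerts$negative_examples <- chr_list(raw$alerts, "negative_examples")

  kb <- structure(list(
    metadata = raw$metadata,
    domains = domains, groups = groups, subgroups = subgroups,
    mies = mies, alerts = alerts,
    source_path = source_path
  ), class = "alert_kb")

  check_kb_structure(kb)
  kb
}

## Hard structural invariants; violation is an error (not a report entry).
check_kb_structure <- function(kb) {
  dup <- function(x) unique(x[duplicated(x)])
  for (lev in c("domains", "groups", "subgroups", "mies", "alerts")) {
    d <- dup(kb[[lev]]$id)
    if (length(d))
      stop("duplicate ", lev, " id(s): ", paste(d, collapse = ", "))
  }
  all_ids <- c(as.character(kb$domains$id), kb$groups$id, kb$subgroups$id,
               kb$mies$id, kb$alerts$id)
  d <- all_ids[duplicated(all_ids)]
  if (length(d)) stop("id(s) reused across tiers: ", paste(unique(d), collapse = ", "))

  miss <- setdiff(kb$groups$domain_id, kb$domains$id)
  if (length(miss))
    stop("group(s) reference unknown domain_id: ", paste(miss, collapse = ", "))
  miss <- setdiff(kb$subgroups$group_id, kb$groups$id)
  if (length(miss))
    stop("subgroup(s) reference unknown group_id: ", paste(miss, collapse = ", "))
  miss <- setdiff(kb$mies$subgroup_id, kb$subgroups$id)
  if (length(miss))
    stop("MIE(s) reference unknown subgroup_id: ", paste(miss, collapse = ", "))
  miss <- setdiff(kb$alerts$mie_id, kb$mies$id)
  if (length(miss))
    stop("alert(s) reference unknown mie_id: ", paste(miss, collapse = ", "))

  ## dotted-code prefix consistency ("3.3.1" sits under "3.3" under 3)
  bad <- kb$groups$id[sub("\\..*$", "", kb$groups$id) != as.character(kb$groups$domain_id)]
  if (length(bad))
    stop("group id(s) whose prefix does not match their domain: ",
         paste(bad, collapse = ", "))
  bad <- kb$subgroups$id[sub("\\.[0-9]+$", "", kb$subgroups$id) != kb$subgroups$group_id]
  if (length(bad))
    stop("subgroup id(s) whose prefix does not match their group: ",
         paste(bad, collapse = ", "))

  for (i in seq_len(nrow(kb$alerts))) {
    seqs <- kb$alerts$smarts_sequence[[i]]
    if (length(seqs) < 1L)
      stop("alert ", kb$alerts$id[i], " has an empty smarts_sequence")
    pats <- c(seqs, kb$alerts$exclusions[[i]])
    ok <- smarts_valid(pats)
    if (!all(ok))
      stop("alert ", kb$alerts$id[i], " has invalid SMARTS: ",
           paste(pats[!ok], collapse = " ; "))
    if (length(kb$alerts$taxa[[i]]) == 0L)
      stop("alert ", kb$alerts$id[i], " has no taxonomic applicability labels")
  }
  invisible(kb)
}

#' The core alert knowledge base shipped with the package
#'
#' Loads the bundled core alert set: the full 3-domain / 10-group /
#' 25-subgroup scheme skeleton plus 34 authored alerts spanning all three
#' Tier 1 domains (Verhaar-derived narcosis rules, soft/hard electrophiles,
#' radical mechanisms, acetylcholinesterase inhibition, photosystem II
#' inhibition, ion-channel modulation and the six amino-acid-biosynthesis
#' alerts). The result is cached for the session.
#'
#' @return an `alert_kb` object.
#' @export
core_kb <- function() {
  if (is.null(.aquaprof_env$core_kb)) {
    path <- system.file("extdata", "core_kb.yaml", package = "aquaprof")
    if (!nzchar(path)) stop("bundled core KB not found; is aquaprof installed?")
    .aquaprof_env$core_kb <- load_kb(path)
  }
  .aquaprof_env$core_kb
}

.aquaprof_env <- new.env(parent = emptyenv())

#' Serialize an alert knowledge base
#'
#' Writes an `alert_kb` back to YAML or JSON (chosen by extension). A KB
#' round-trips: `load_kb(write_kb(kb, f))` is structurally identical to
#' `kb`.
#'
#' @param kb an `alert_kb`.
#' @param path output file path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  stopifnot(inherits(kb, "alert_kb"))
  listify <- function(df, fields) {
    lapply(seq_len(nrow(df)), function(i) {
      rec <- list()
      for (f in fields) {
        v <- df[[f]][i]
        if (is.list(v)) v <- as.list(v[[1]]) else v <- v[[1]]
        rec[[f]] <- v
      }
      rec
    })
  }
  out <- list(
    metadata = kb$metadata,
    domains = listify(kb$domains, c("id", "name")),
    groups = listify(kb$groups, c("id", "name", "domain_id")),
    subgroups = listify(kb$subgroups, c("id", "name", "group_id")),
    mies = listify(kb$mies, c("id", "name", "subgroup_id", "description")),
    alerts = listify(kb$alerts, c("id", "name", "mie_id", "smarts_sequence",
                                  "exclusions", "taxa", "notes",
                                  "positive_examples", "negative_examples"))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Validate a knowledge base against its own examples
#'
#' Runs the soft, report-style checks: SMARTS compile status per alert,
#' whether each embedded positive example matches its alert's full SMARTS
#' sequence (net of exclusions), and whether each negative example is
#' correctly rejected. Failures are collected, never raised, so a partially
#' broken KB can be inspected in full.
#'
#' @param kb an `alert_kb`.
#' @return an object of class `kb_validation`: a data.frame with columns
#'   `alert_id`, `check` (`smarts_compile`, `positive_example`,
#'   `negative_example`), `detail` and `ok`. `all(x$ok)` iff the KB
#'   self-validates.
#' @examples
#' rep <- validate_kb(core_kb())
#' summary(rep)
#' @export
validate_kb <- function(kb) {
  stopifnot(inherits(kb, "alert_kb"))
  rows <- list()
  add <- function(alert_id, check, detail, ok) {
    rows[[length(rows) + 1L]] <<- data.frame(
      alert_id = alert_id, check = check, detail = detail, ok = ok,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(kb$alerts))) {
    aid <- kb$alerts$id[i]
    pats <- c(kb$alerts$smarts_sequence[[i]], kb$alerts$exclusions[[i]])
    ok <- smarts_valid(pats)
    for (k in seq_along(pats)) add(aid, "smarts_compile", pats[k], ok[k])
    if (!all(ok)) next
    alert <- kb_alert(kb, aid)
    for (p in kb$alerts$positive_examples[[i]]) {
      hit <- alert_matches_smiles(p, alert)
      add(aid, "positive_example", p, isTRUE(hit))
    }
    for (p in kb$alerts$negative_examples[[i]]) {
      hit <- alert_matches_smiles(p, alert)
      add(aid, "negative_example", p, isFALSE(hit))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(alert_id = character(0), check = character(0),
               detail = character(0), ok = logical(0), stringsAsFactors = FALSE)
  class(out) <- c("kb_validation", "data.frame")
  out
}

## Extract one alert record (with lineage) as a plain list.
kb_alert <- function(kb, alert_id) {
  i <- match(alert_id, kb$alerts$id)
  if (is.na(i)) stop("unknown alert id: ", alert_id)
  mie <- kb$mies[match(kb$alerts$mie_id[i], kb$mies$id), ]
  sg <- kb$subgroups[match(mie$subgroup_id, kb$subgroups$id), ]
  gr <- kb$groups[match(sg$group_id, kb$groups$id), ]
  list(
    id = kb$alerts$id[i], name = kb$alerts$name[i],
    smarts_sequence = kb$alerts$smarts_sequence[[i]],
    exclusions = kb$alerts$exclusions[[i]],
    taxa = kb$alerts$taxa[[i]],
    mie_id = mie$id, mie_name = mie$name,
    subgroup_id = sg$id, subgroup_name = sg$name,
    group_id = gr$id, group_name = gr$name,
    domain_id = gr$domain_id,
    domain_name = kb$domains$name[match(gr$domain_id, kb$domains$id)]
  )
}

## TRUE iff every SMARTS in the sequence embeds and no exclusion does.
alert_matches_smiles <- function(smiles, alert) {
  counts <- tryCatch(
    count_smarts_matches(smiles, c(alert$smarts_sequence, alert$exclusions)),
    error = function(e) NULL)
  if (is.null(counts)) return(NA)
  nseq <- length(alert$smarts_sequence)
  all(counts[seq_len(nseq)] > 0L) &&
    (length(alert$exclusions) == 0L || all(counts[-seq_len(nseq)] == 0L))
}

#' Summarize a knowledge base by tier
#'
#' One row per subgroup with counts of distinct MIEs (`n_mie`) and alerts
#' (`n_sa`) beneath it, in the layout of the published scheme-overview
#' table; group, domain and grand totals are attached as attributes.
#'
#' @param kb an `alert_kb`.
#' @return a `tier_summary` data.frame with columns `domain_id`,
#'   `domain_name`, `group_id`, `group_name`, `subgroup_id`,
#'   `subgroup_name`, `n_mie`, `n_sa`, plus attributes `group_totals`,
#'   `domain_totals` and `grand_total`.
#' @examples
#' s <- kb_summary(core_kb())
#' s[s$subgroup_id == "3.3.1", ]
#' attr(s, "grand_total")
#' @export
kb_summary <- function(kb) {
  stopifnot(inherits(kb, "alert_kb"))
  sg <- kb$subgroups
  gr <- kb$groups[match(sg$group_id, kb$groups$id), ]
  mie_by_sg <- table(kb$mies$subgroup_id)
  alert_sg <- kb$mies$subgroup_id[match(kb$alerts$mie_id, kb$mies$id)]
  sa_by_sg <- table(alert_sg)
  out <- data.frame(
    domain_id = gr$domain_id,
    domain_name = kb$domains$name[match(gr$domain_id, kb$domains$id)],
    group_id = gr$id, group_name = gr$name,
    subgroup_id = sg$id, subgroup_name = sg$name,
    n_mie = as.integer(mie_by_sg[sg$id]),
    n_sa = as.integer(sa_by_sg[sg$id]),
    stringsAsFactors = FALSE
  )
  out$n_mie[is.na(out$n_mie)] <- 0L
  out$n_sa[is.na(out$n_sa)] <- 0L
  out <- out[order(numeric_version(gsub("[^0-9.]", "", out$subgroup_id))), ]
  rownames(out) <- NULL
  attr(out, "group_totals") <- stats::aggregate(
    cbind(n_mie, n_sa) ~ group_id, data = out, FUN = sum)
  attr(out, "domain_totals") <- stats::aggregate(
    cbind(n_mie, n_sa) ~ domain_id, data = out, FUN = sum)
  attr(out, "grand_total") <- c(n_mie = sum(out$n_mie), n_sa = sum(out$n_sa))
  class(out) <- c("tier_summary", "data.frame")
  out
}

#' @export
print.alert_kb <- function(x, ...) {
  meta <- x$metadata
  cat("Alert knowledge base:", if (!is.null(meta$name)) meta$name else "<unnamed>", "\n")
  if (!is.null(meta$version)) cat("  version:", meta$version, "\n")
  cat(sprintf("  %d domains, %d groups, %d subgroups, %d MIEs, %d alerts\n",
              nrow(x$domains), nrow(x$groups), nrow(x$subgroups),
              nrow(x$mies), nrow(x$alerts)))
  invisible(x)
}

#' @export
print.kb_validation <- function(x, ...) {
  bad <- x[!x$ok, , drop = FALSE]
  cat(sprintf("KB validation: %d checks, %d failure(s)\n", nrow(x), nrow(bad)))
  if (nrow(bad)) print.data.frame(bad, row.names = FALSE)
  invisible(x)
}

#' @export
summary.kb_validation <- function(object, ...) {
  c(checks = nrow(object), failures = sum(!object$ok))
}

#' @export
print.tier_summary <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  gt <- attr(x, "grand_total")
  cat(sprintf("Grand total: %d MIEs, %d alerts\n", gt[["n_mie"]], gt[["n_sa"]]))
  invisible(x)
}
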