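## Two-phase sequential profiling. Phase 1 evaluates, concurrently, every
## alert from the reactive and specific domains plus mechanistic group 1.2
## (enhanced narcosis); compounds are multi-labeled with every hit. Only
## compounds with no phase-1 match fall through to phase 2, the nonpolar
## narcosis rules (group 1.1). A compound with any reactive, specific or
## enhanced-narcosis assignment therefore can never also be labeled a
## nonpolar narcotic.

## Alert ids evaluated in each phase.
phase_alert_ids <- function(kb) {
  lineage <- alert_lineage(kb)
  phase1 <- lineage$alert_id[lineage$domain_id %in% c(2L, 3L) | lineage$group_id == "1.2"]
  phase2 <- lineage$alert_id[lineage$group_id == "1.1"]
  list(phase1 = phase1, phase2 = phase2)
}

## Lineage table: one row per alert with its full tier ancestry.
alert_lineage <- function(kb) {
  mie <- kb$mies[match(kb$alerts$mie_id, kb$mies$id), ]
  sg <- kb$subgroups[match(mie$subgroup_id, kb$subgroups$id), ]
  gr <- kb$groups[match(sg$group_id, kb$groups$id), ]
  data.frame(
    alert_id = kb$alerts$id, alert_name = kb$alerts$name,
    mie_id = mie$id, mie_name = mie$name,
    subgroup_id = sg$id, subgroup_name = sg$name,
    group_id = gr$id, group_name = gr$name,
    domain_id = gr$domain_id,
    domain_name = kb$domains$name[match(gr$domain_id, kb$domains$id)],
    stringsAsFactors = FALSE
  )
}

#' Match a single alert against a compound
#'
#' An alert matches iff every SMARTS in its (ordered, conjunctive)
#' `smarts_sequence` has at least one embedding in the molecule and none of
#' its exclusion patterns match. Duplicate embeddings of one SMARTS count
#' as a single match.
#'
#' @param parent_smiles standardized single-fragment SMILES.
#' @param kb an `alert_kb`.
#' @param alert_id id of the alert to evaluate.
#' @param with_atoms if `TRUE`, report the atom indices of the first
#'   embedding of the first SMARTS in the sequence.
#' @return `NULL` if no match; otherwise a list of class `alert_match`
#'   carrying the alert id, full tier lineage, taxa, and (optionally)
#'   `matched_atom_indices`.
#' @examples
#' match_alert("C=CC(=O)OC", core_kb(), "2.1.1-SA01")
#' @export
match_alert <- function(parent_smiles, kb, alert_id, with_atoms = FALSE) {
  alert <- kb_alert(kb, alert_id)
  hit <- alert_matches_smiles(parent_smiles, alert)
  if (!isTRUE(hit)) return(NULL)
  atoms <- if (with_atoms)
    first_match_atoms(parent_smiles, alert$smarts_sequence[[1L]]) else integer(0)
  structure(list(
    alert_id = alert$id, alert_name = alert$name,
    mie_id = alert$mie_id, mie_name = alert$mie_name,
    subgroup_id = alert$subgroup_id, subgroup_name = alert$subgroup_name,
    group_id = alert$group_id, group_name = alert$group_name,
    domain_id = alert$domain_id, domain_name = alert$domain_name,
    taxa = alert$taxa,
    matched_atom_indices = atoms
  ), class = "alert_match")
}

#' Profile one standardized compound through the two-phase workflow
#'
#' @param parent_smiles standardized single-fragment SMILES.
#' @param kb an `alert_kb`.
#' @param record_id identifier carried into the result.
#' @param with_atoms passed to [match_alert()].
#' @return a list of class `profile_result`: `record_id`, `parent_smiles`,
#'   `matches` (list of `alert_match`, possibly empty), `phase` (1, 2 or
#'   `NA` when unmatched) and `status` (`"classified"`/`"unclassified"`).
#' @examples
#' profile_compound("CCCCCC", core_kb())      # nonpolar narcosis, phase 2
#' profile_compound("C=CC(=O)OC", core_kb())  # reactive (+ ester), phase 1
#' @export
profile_compound <- function(parent_smiles, kb, record_id = parent_smiles,
                             with_atoms = FALSE) {
  ids <- phase_alert_ids(kb)
  run <- function(alert_ids) {
    hits <- lapply(alert_ids, function(aid)
      match_alert(parent_smiles, kb, aid, with_atoms = with_atoms))
    hits[!vapply(hits, is.null, logical(1))]
  }
  matches <- run(ids$phase1)
  phase <- if (length(matches)) 1L else NA_integer_
  if (!length(matches)) {
    matches <- run(ids$phase2)
    if (length(matches)) phase <- 2L
  }
  structure(list(
    record_id = record_id,
    parent_smiles = parent_smiles,
    matches = matches,
    phase = phase,
    status = if (length(matches)) "classified" else "unclassified"
  ), class = "profile_result")
}

#' Profile an inventory of standardized compounds
#'
#' Stateless element-wise application of [profile_compound()]; the result
#' order matches the input order and per-compound results are independent
#' of batch composition.
#'
#' @param compounds a `preprocessed_inventory`, or a data.frame with
#'   columns `record_id` and `parent_smiles`.
#' @param kb an `alert_kb`.
#' @param with_atoms passed through to [match_alert()].
#' @return an object of class `profile_set`: a list of `profile_result`.
#' @export
profile_inventory <- function(compounds, kb, with_atoms = FALSE) {
  if (inherits(compounds, "preprocessed_inventory")) compounds <- compounds$compounds
  stopifnot(is.data.frame(compounds),
            all(c("record_id", "parent_smiles") %in% names(compounds)))
  out <- lapply(seq_len(nrow(compounds)), function(i)
    profile_compound(compounds$parent_smiles[i], kb,
                     record_id = compounds$record_id[i],
                     with_atoms = with_atoms))
  structure(out, class = "profile_set")
}

#' Long-form results table
#'
#' Flattens profile results into the tool's long output layout: one row per
#' (compound, matched alert); unclassified compounds emit a single row with
#' empty alert fields. Taxa are semicolon-joined.
#'
#' @param results a `profile_set` or list of `profile_result`.
#' @return data.frame with columns `record_id`, `parent_smiles`, `status`,
#'   `phase`, `alert_id`, `alert_name`, `mie_id`, `mie_name`,
#'   `subgroup_id`, `subgroup_name`, `group_id`, `group_name`, `domain_id`,
#'   `domain_name`, `taxa`.
#' @export
results_table <- function(results) {
  rows <- lapply(results, function(r) {
    base <- data.frame(record_id = r$record_id, parent_smiles = r$parent_smiles,
                       status = r$status, phase = r$phase,
                       stringsAsFactors = FALSE)
    if (!length(r$matches)) {
      empty <- data.frame(alert_id = "", alert_name = "", mie_id = "",
                          mie_name = "", subgroup_id = "", subgroup_name = "",
                          group_id = "", group_name = "",
                          domain_id = NA_integer_, domain_name = "", taxa = "",
                          stringsAsFactors = FALSE)
      return(cbind(base, empty))
    }
    do.call(rbind, lapply(r$matches, function(m) cbind(base, data.frame(
      alert_id = m$alert_id, alert_name = m$alert_name,
      mie_id = m$mie_id, mie_name = m$mie_name,
      subgroup_id = m$subgroup_id, subgroup_name = m$subgroup_name,
      group_id = m$group_id, group_name = m$group_name,
      domain_id = m$domain_id, domain_name = m$domain_name,
      taxa = paste(m$taxa, collapse = ";"),
      stringsAsFactors = FALSE))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.profile_result <- function(x, ...) {
  cat(sprintf("<%s> %s: %s", x$record_id, x$parent_smiles, x$status))
  if (x$status == "classified") {
    cat(sprintf(" (phase %d)\n", x$phase))
    for (m in x$matches)
      cat(sprintf("  %-12s %s [%s %s / %s]\n", m$alert_id, m$alert_name,
                  m$domain_name, m$subgroup_id,
                  paste(m$taxa, collapse = "; ")))
  } else cat("\n")
  invisible(x)
}

#' @export
print.profile_set <- function(x, ...) {
  st <- vapply(x, `[[`, character(1), "status")
  cat(sprintf("Profile set: %d compounds, %d classified, %d unclassified\n",
              length(x), sum(st == "classified"), sum(st == "unclassified")))
  invisible(x)
}

#' @export
`[.profile_set` <- function(x, i) structure(unclass(x)[i], class = "profile_set")

#' @export
as.data.frame.profile_set <- function(x, ...) results_table(x)
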