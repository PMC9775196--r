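# Shared fixtures built in code. core_kb() caches per session, so repeated
# calls across test files are cheap.

# Minimal valid KB skeleton (3 domains, one branch, no alerts) for
# structural tests; returned as a plain list ready to serialize or mutate.
minimal_kb_list <- function() {
  list(
    metadata = list(name = "mini", version = "1"),
    domains = list(list(id = 1L, name = "narcosis"),
                   list(id = 2L, name = "reactive"),
                   list(id = 3L, name = "specific")),
    groups = list(list(id = "1.1", name = "nonpolar narcosis", domain_id = 1L)),
    subgroups = list(list(id = "1.1.1", name = "nonpolar", group_id = "1.1")),
    mies = list(),
    alerts = list()
  )
}

write_kb_yaml <- function(kb_list, path = tempfile(fileext = ".yaml")) {
  yaml::write_yaml(kb_list, path)
  path
}

# Brute-force reference classifier: flat evaluation of every KB alert
# through the ChemmineR/SDF route, then the phase rule applied post hoc.
# Deliberately shares no control flow with profile_compound().
oracle_profile <- function(smiles, kb) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  hits <- character(0)
  for (j in seq_len(nrow(kb$alerts))) {
    seqs <- kb$alerts$smarts_sequence[[j]]
    excl <- kb$alerts$exclusions[[j]]
    cnt <- vapply(c(seqs, excl), function(p)
      suppressWarnings(as.integer(ChemmineR::smartsSearchOB(sdf, p))), integer(1))
    if (all(cnt[seq_along(seqs)] > 0L) &&
        (length(excl) == 0L || all(cnt[-seq_along(seqs)] == 0L)))
      hits <- c(hits, kb$alerts$id[j])
  }
  lineage <- aquaprof:::alert_lineage(kb)
  li <- lineage[match(hits, lineage$alert_id), , drop = FALSE]
  phase1 <- hits[li$domain_id %in% c(2L, 3L) | li$group_id == "1.2"]
  if (length(phase1)) return(list(alerts = sort(phase1), phase = 1L))
  phase2 <- hits[li$group_id == "1.1"]
  if (length(phase2)) return(list(alerts = sort(phase2), phase = 2L))
  list(alerts = character(0), phase = NA_integer_)
}

matched_ids <- function(result) {
  sort(vapply(result$matches, `[[`, character(1), "alert_id"))
}
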