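## Desk-scale test inputs: a curated mini-inventory in which every core-KB
## alert has at least one exemplar and the complete expected outcome
## (status, alert set, phase) is recorded; plus seeded decoy generation and
## preprocessing probes (salt, inorganic, duplicate).

## Curated exemplars. expected_alerts is the COMPLETE expected match set
## under the two-phase rule (multi-label rows list every alert the
## structure is expected to hit in its phase); derived from the alert
## definitions, not from running the profiler.
curated_manifest <- function() {
  row <- function(id, smiles, alerts, phase, notes = "") {
    data.frame(record_id = id, smiles = smiles,
               expected_status = if (length(alerts)) "classified" else "unclassified",
               expected_alert_ids = paste(alerts, collapse = ";"),
               expected_phase = if (length(alerts)) phase else NA_integer_,
               notes = notes, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    row("hexane", "CCCCCC", "1.1.1-SA01", 2L),
    row("o-xylene", "Cc1ccccc1C", "1.1.1-SA02", 2L),
    row("1-chlorobutane", "CCCCCl", "1.1.1-SA03", 2L),
    row("1,4-dichlorobenzene", "Clc1ccc(Cl)cc1", "1.1.1-SA04", 2L),
    row("1-butanol", "CCCCO", "1.1.1-SA05", 2L),
    row("diethyl-ether", "CCOCC", "1.1.1-SA06", 2L),
    row("4-chlorophenol", "Oc1ccc(Cl)cc1", "1.2.1-SA01", 1L),
    row("aniline", "Nc1ccccc1", "1.2.1-SA02", 1L),
    row("2-nitrotoluene", "Cc1ccccc1[N+](=O)[O-]", "1.2.1-SA03", 1L),
    row("cetrimonium", "CCCCCCCCCCCCCCCC[N+](C)(C)C", "1.2.1-SA04", 1L,
        "quaternary ammonium surfactant, stepwise two-SMARTS alert"),
    row("hexylamine", "CCCCCCN", "1.2.2-SA01", 1L),
    row("ethyl-acetate", "CC(=O)OCC", "1.2.3-SA01", 1L),
    row("methyl-acrylate", "C=CC(=O)OC",
        c("1.2.3-SA01", "2.1.1-SA01"), 1L,
        "Michael acceptor that is also a carboxylic acid ester"),
    row("acrylonitrile", "C=CC#N", "2.1.1-SA02", 1L),
    row("chloroacetone", "ClCC(C)=O", "2.1.1-SA03", 1L),
    row("ethyl-isothiocyanate", "CCN=C=S", "2.1.1-SA04", 1L),
    row("acetaldehyde", "CC=O", "2.1.2-SA01", 1L),
    row("propylene-oxide", "CC1CO1", "2.1.2-SA02", 1L,
        "phase-1 epoxide match suppresses the phase-2 aliphatic ether rule"),
    row("1,2-dichloroethane", "ClCCCl", "2.1.3-SA01", 1L,
        "phase-1 pre-reactive match suppresses the phase-2 haloalkane rule"),
    row("isopropyl-hydroperoxide", "CC(C)OO", "2.3.1-SA01", 1L),
    row("benzoquinone", "O=C1C=CC(=O)C=C1",
        c("2.1.1-SA01", "2.3.2-SA01"), 1L,
        "quinones are Michael acceptors as well as redox cyclers"),
    row("5-nitrofuran", "O=[N+]([O-])c1ccco1",
        c("1.2.1-SA03", "2.3.2-SA02"), 1L,
        "nitroheteroaromatic hits the aromatic-nitro narcosis rule too"),
    row("chloroform", "ClC(Cl)Cl", "2.3.3-SA01", 1L),
    row("parathion", "CCOP(=S)(OCC)Oc1ccc([N+](=O)[O-])cc1",
        c("1.2.1-SA03", "3.1.1-SA01"), 1L,
        "nitrophenyl ring carries the aromatic-nitro rule"),
    row("carbaryl", "CNC(=O)Oc1cccc2ccccc12", "3.1.1-SA02", 1L),
    row("atrazine", "CCNc1nc(Cl)nc(NC(C)C)n1", "3.1.2-SA01", 1L),
    row("diuron", "CN(C)C(=O)Nc1ccc(Cl)c(Cl)c1", "3.1.2-SA02", 1L),
    row("DDT", "ClC(Cl)(Cl)C(c1ccc(Cl)cc1)c1ccc(Cl)cc1", "3.2.1-SA01", 1L),
    row("flumetsulam", "Cc1ccn2c(n1)nc(n2)S(=O)(=O)Nc1c(F)cccc1F",
        "3.3.1-SA01", 1L, "acetolactate synthase form A"),
    row("imazapyr", "CC(C)C1(C)N=C(c2ncccc2C(=O)O)NC1=O",
        "3.3.1-SA02", 1L, "acetolactate synthase form B"),
    row("chlorsulfuron", "COc1cc(C)nc(NC(=O)NS(=O)(=O)c2ccccc2Cl)n1",
        "3.3.1-SA03", 1L, "acetolactate synthase form C"),
    row("bispyribac-acid", "COc1cc(OC)nc(Oc2ccccc2C(=O)O)n1",
        "3.3.1-SA04", 1L, "acetolactate synthase form D"),
    row("glyphosate", "OC(=O)CNCP(=O)(O)O", "3.3.1-SA05", 1L,
        "EPSP synthase inhibitor"),
    row("glufosinate", "CP(=O)(O)CCC(N)C(=O)O", "3.3.1-SA06", 1L,
        "glutamine synthetase inhibitor"),
    row("urea", "NC(=O)N", character(0), NA_integer_),
    row("acetamide", "CC(=O)N", character(0), NA_integer_),
    row("benzoic-acid", "OC(=O)c1ccccc1", character(0), NA_integer_)
  ))
}

## Preprocessing probes appended by build_fixture_inventory; these exercise
## salt stripping, inorganic rejection and duplicate collapse, so their
## expected_status uses the extended vocabulary {classified, unclassified,
## rejected}.
prep_probes <- function() {
  data.frame(
    record_id = c("ethanol-hydrochloride", "sodium-chloride", "ethanol-respelled"),
    smiles = c("CCO.Cl", "[Na+].[Cl-]", "OCC"),
    expected_status = c("classified", "rejected", "rejected"),
    expected_alert_ids = c("1.1.1-SA05", "", ""),
    expected_phase = c(2L, NA_integer_, NA_integer_),
    notes = c("salt probe: parent is ethanol",
              "inorganic probe: no carbon-containing fragment",
              "duplicate probe: same parent as the salt probe"),
    stringsAsFactors = FALSE
  )
}

#' Build the fixture mini-inventory and its classification manifest
#'
#' Assembles the curated exemplar set (every core-KB alert covered by at
#' least one structure with a fully specified expected outcome), the
#' preprocessing probes (salt, inorganic, duplicate), and `n_decoys`
#' generated narcosis-inert structures: linear alkanes (C7-C12) and linear
#' primary alcohols (C5-C12), whose expected classification (nonpolar
#' narcosis, phase 2) is derivable without ambiguity. Generation is
#' deterministic for a fixed seed.
#'
#' @param seed integer seed for decoy sampling.
#' @param n_decoys number of decoy structures (>= 0).
#' @return list with elements `records` (data.frame `record_id`, `smiles`,
#'   `source`) ready for [preprocess_inventory()], and `manifest`
#'   (data.frame `record_id`, `smiles`, `expected_status`,
#'   `expected_alert_ids`, `expected_phase`, `notes`).
#' @examples
#' fx <- build_fixture_inventory(seed = 1, n_decoys = 5)
#' nrow(fx$records)
#' @export
build_fixture_inventory <- function(seed = 1L, n_decoys = 0L) {
  stopifnot(n_decoys >= 0L)
  manifest <- rbind(curated_manifest(), prep_probes())
  if (n_decoys > 0L) {
    pool <- c(
      vapply(7:12, function(n) strrep("C", n), character(1)),
      vapply(5:12, function(n) paste0(strrep("C", n), "O"), character(1))
    )
    withr_seed <- function(expr) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      expr
    }
    picks <- withr_seed(sample(pool, n_decoys, replace = n_decoys > length(pool)))
    ## duplicates among decoys are legitimate preprocessing fodder: only the
    ## first copy of each structure survives deduplication
    first_copy <- !duplicated(picks)
    decoys <- data.frame(
      record_id = sprintf("decoy%03d", seq_len(n_decoys)),
      smiles = picks,
      expected_status = ifelse(first_copy, "classified", "rejected"),
      expected_alert_ids = ifelse(!first_copy, "",
                                  ifelse(grepl("O$", picks), "1.1.1-SA05", "1.1.1-SA01")),
      expected_phase = ifelse(first_copy, 2L, NA_integer_),
      notes = ifelse(first_copy, "generated narcosis decoy", "duplicate decoy"),
      stringsAsFactors = FALSE
    )
    manifest <- rbind(manifest, decoys)
  }
  records <- data.frame(record_id = manifest$record_id,
                        smiles = manifest$smiles,
                        source = "fixture", stringsAsFactors = FALSE)
  list(records = records, manifest = manifest)
}

#' Extract the per-alert example manifest from a knowledge base
#'
#' Pulls every positive and negative example embedded in the KB's alerts
#' into one runnable table (the per-alert oracle suite). Alerts lacking a
#' positive example are listed in the `gaps` attribute.
#'
#' @param kb an `alert_kb`.
#' @return data.frame with columns `record_id`, `alert_id`, `kind`
#'   (`"positive"`/`"negative"`), `smiles`; attribute `gaps` names alerts
#'   without positives.
#' @export
positive_examples <- function(kb) {
  stopifnot(inherits(kb, "alert_kb"))
  rows <- list()
  for (i in seq_len(nrow(kb$alerts))) {
    aid <- kb$alerts$id[i]
    pos <- kb$alerts$positive_examples[[i]]
    neg <- kb$alerts$negative_examples[[i]]
    for (k in seq_along(pos))
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = sprintf("%s-pos%d", aid, k), alert_id = aid,
        kind = "positive", smiles = pos[k], stringsAsFactors = FALSE)
    for (k in seq_along(neg))
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = sprintf("%s-neg%d", aid, k), alert_id = aid,
        kind = "negative", smiles = neg[k], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  n_pos <- vapply(kb$alerts$positive_examples, length, integer(1))
  attr(out, "gaps") <- kb$alerts$id[n_pos == 0L]
  out
}
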