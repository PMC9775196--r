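test_that("single-alert matching follows the SMARTS conjunction semantics", {
  kb <- core_kb()
  # methyl acrylate carries the alpha,beta-unsaturated carbonyl
  m <- match_alert("C=CC(=O)OC", kb, "2.1.1-SA01")
  expect_s3_class(m, "alert_match")
  expect_equal(m$subgroup_id, "2.1.1")
  expect_equal(m$domain_name, "reactive")
  # ethane carries nothing of the sort
  expect_null(match_alert("CC", kb, "2.1.1-SA01"))
  # a sulfonylurea herbicide matches the acetolactate-synthase form-C alert
  m <- match_alert("COc1cc(C)nc(NC(=O)NS(=O)(=O)c2ccccc2Cl)n1", kb, "3.3.1-SA03")
  expect_equal(m$subgroup_id, "3.3.1")
  expect_equal(m$domain_name, "specific")
})

test_that("match lineage is mutually consistent and taxa are carried", {
  kb <- core_kb()
  m <- match_alert("CCOP(=S)(OCC)Oc1ccc([N+](=O)[O-])cc1", kb, "3.1.1-SA01",
                   with_atoms = TRUE)
  expect_equal(m$mie_id, "M3.1.1-1")
  expect_equal(m$group_id, "3.1")
  expect_equal(m$domain_id, 3L)
  expect_true(startsWith(m$subgroup_id, m$group_id))
  expect_equal(m$taxa, "Metazoa")
  expect_gt(length(m$matched_atom_indices), 0L)
})

test_that("a multi-SMARTS (stepwise) alert requires every pattern", {
  kb <- core_kb()
  # quaternary ammonium surfactant: head group AND long tail
  expect_s3_class(match_alert("CCCCCCCCCCCCCCCC[N+](C)(C)C", kb, "1.2.1-SA04"),
                  "alert_match")
  expect_null(match_alert("C[N+](C)(C)C", kb, "1.2.1-SA04"))       # head only
  expect_null(match_alert("CCCCCCCCCCCCCCCCO", kb, "1.2.1-SA04"))  # tail only
})

test_that("exclusion patterns veto an otherwise matching alert", {
  kb <- core_kb()
  # salicylic acid: phenol present but the carbonyl exclusion vetoes
  expect_null(match_alert("OC(=O)c1ccccc1O", kb, "1.2.1-SA01"))
  expect_s3_class(match_alert("Oc1ccccc1", kb, "1.2.1-SA01"), "alert_match")
})

test_that("the two-phase workflow assigns hexane to nonpolar narcosis in phase 2", {
  r <- profile_compound("CCCCCC", core_kb())
  expect_equal(r$status, "classified")
  expect_equal(r$phase, 2L)
  expect_equal(matched_ids(r), "1.1.1-SA01")
  expect_equal(r$matches[[1]]$subgroup_id, "1.1.1")
})

test_that("a phase-1 hit suppresses all nonpolar narcosis assignments", {
  kb <- core_kb()
  r <- profile_compound("C=CC(=O)OC", kb)
  expect_equal(r$phase, 1L)
  expect_true(all(vapply(r$matches, `[[`, character(1), "group_id") != "1.1"))
  expect_true(any(vapply(r$matches, `[[`, integer(1), "domain_id") == 2L))
  # 1,2-dichloroethane matches the haloalkane narcosis rule in isolation,
  # but its pre-reactive phase-1 hit must mask it
  r <- profile_compound("ClCCCl", kb)
  expect_equal(r$phase, 1L)
  expect_equal(matched_ids(r), "2.1.3-SA01")
})

test_that("compounds matching nothing are unclassified with empty matches", {
  r <- profile_compound("NC(=O)N", core_kb())
  expect_equal(r$status, "unclassified")
  expect_length(r$matches, 0L)
  expect_true(is.na(r$phase))
})

test_that("an engineered bifunctional molecule accrues both phase-1 matches", {
  # glycidyl acrylate: Michael acceptor AND epoxide (plus the ester rule)
  r <- profile_compound("C=CC(=O)OCC1CO1", core_kb())
  expect_equal(r$phase, 1L)
  expect_true(all(c("2.1.1-SA01", "2.1.2-SA02") %in% matched_ids(r)))
  expect_gte(length(r$matches), 2L)
})

test_that("profiling an inventory is element-wise, order-preserving and stateless", {
  kb <- core_kb()
  comp <- data.frame(record_id = c("a", "b"),
                     parent_smiles = c("CCCCCC", "C=CC(=O)OC"))
  batch <- profile_inventory(comp, kb)
  solo_a <- profile_compound("CCCCCC", kb, record_id = "a")
  solo_b <- profile_compound("C=CC(=O)OC", kb, record_id = "b")
  expect_equal(vapply(batch, `[[`, character(1), "record_id"), c("a", "b"))
  expect_equal(matched_ids(batch[[1]]), matched_ids(solo_a))
  expect_equal(matched_ids(batch[[2]]), matched_ids(solo_b))
  expect_length(profile_inventory(
    data.frame(record_id = character(0), parent_smiles = character(0)), kb), 0L)
})

test_that("profiler results equal the brute-force oracle on the fixture set", {
  kb <- core_kb()
  fx <- build_fixture_inventory(seed = 1, n_decoys = 0)
  pp <- preprocess_inventory(fx$records)
  ps <- profile_inventory(pp, kb)
  for (i in seq_along(ps)) {
    want <- oracle_profile(pp$compounds$parent_smiles[i], kb)
    expect_equal(matched_ids(ps[[i]]), want$alerts,
                 info = pp$compounds$record_id[i])
    expect_equal(ps[[i]]$phase, want$phase, info = pp$compounds$record_id[i])
  }
})

test_that("per-result lineage breadth is monotone across tiers", {
  fx <- build_fixture_inventory(seed = 2, n_decoys = 6)
  pp <- preprocess_inventory(fx$records)
  ps <- profile_inventory(pp, core_kb())
  for (r in ps) {
    if (!length(r$matches)) next
    nd <- length(unique(vapply(r$matches, `[[`, integer(1), "domain_id")))
    ng <- length(unique(vapply(r$matches, `[[`, character(1), "group_id")))
    nsg <- length(unique(vapply(r$matches, `[[`, character(1), "subgroup_id")))
    expect_lte(nd, ng); expect_lte(ng, nsg); expect_lte(nsg, length(r$matches))
  }
})

test_that("the long results table carries one row per match and empty rows for misses", {
  ps <- profile_inventory(data.frame(
    record_id = c("mix", "none"),
    parent_smiles = c("C=CC(=O)OC", "NC(=O)N")), core_kb())
  tab <- results_table(ps)
  expect_equal(sum(tab$record_id == "mix"), 2L)
  expect_equal(sum(tab$record_id == "none"), 1L)
  expect_equal(tab$alert_id[tab$record_id == "none"], "")
  expect_true(all(c("taxa", "domain_name", "mie_name") %in% names(tab)))
})
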