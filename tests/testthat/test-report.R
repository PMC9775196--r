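# tiny hand-built profile results for aggregation tests
fake_match <- function(alert_id, subgroup, group, domain_id, domain_name,
                       taxa = "all taxa and species") {
  structure(list(alert_id = alert_id, alert_name = alert_id,
                 mie_id = paste0("M", subgroup), mie_name = "m",
                 subgroup_id = subgroup, subgroup_name = subgroup,
                 group_id = group, group_name = group,
                 domain_id = domain_id, domain_name = domain_name,
                 taxa = taxa, matched_atom_indices = integer(0)),
            class = "alert_match")
}
fake_result <- function(id, matches, phase = if (length(matches)) 1L else NA_integer_) {
  structure(list(record_id = id, parent_smiles = "C", matches = matches,
                 phase = phase,
                 status = if (length(matches)) "classified" else "unclassified"),
            class = "profile_result")
}
m_narc <- fake_match("1.2.1-SA01", "1.2.1", "1.2", 1L, "narcosis")
m_reac <- fake_match("2.1.1-SA01", "2.1.1", "2.1", 2L, "reactive")
m_spec <- fake_match("3.3.1-SA01", "3.3.1", "3.3", 3L, "specific", taxa = "Viridiplantae")

test_that("coverage summary counts an empty result set as zero with a flag", {
  cs <- coverage_summary(list())
  expect_equal(cs$n_total, 0L)
  expect_equal(cs$pct_unclassified, 0)
  expect_true(cs$empty)
})

test_that("coverage summary tallies statuses and the alert histogram", {
  res <- list(fake_result("a", list(m_reac)),
              fake_result("b", list(m_reac, m_spec)),
              fake_result("c", list()))
  cs <- coverage_summary(res)
  expect_equal(cs$n_total, 3L)
  expect_equal(cs$n_classified, 2L)
  expect_equal(cs$n_unclassified, 1L)
  expect_equal(unname(cs$histogram), c(1L, 1L, 0L))
  expect_equal(sum(cs$histogram), cs$n_classified)
  expect_equal(cs$pct_unclassified, 100 / 3)
  expect_equal(unname(cs$by_domain[["reactive"]]), 2L)
  expect_equal(unname(cs$by_domain[["specific"]]), 1L)
})

test_that("coverage summary is permutation-invariant", {
  res <- list(fake_result("a", list(m_reac)),
              fake_result("b", list(m_reac, m_spec)),
              fake_result("c", list()),
              fake_result("d", list(m_narc)))
  cs1 <- coverage_summary(res)
  cs2 <- coverage_summary(rev(res))
  expect_equal(cs2$histogram, cs1$histogram)
  expect_equal(cs2$by_domain, cs1$by_domain)
  expect_equal(cs2$n_classified, cs1$n_classified)
})

test_that("a single-subgroup compound produces one three-edge flow chain", {
  fl <- sankey_flows(list(fake_result("a", list(m_spec))), "inv")
  expect_equal(nrow(fl), 3L)
  expect_equal(fl$count, rep(1L, 3))
  expect_equal(fl$source_node[fl$level == "inventory>domain"], "inv")
  expect_equal(fl$target_node[fl$level == "group>subgroup"], "3.3.1")
})

test_that("multi-domain compounds multiply lower-tier flow totals", {
  fl <- sankey_flows(list(fake_result("a", list(m_reac, m_spec))), "inv")
  dom <- fl[fl$level == "inventory>domain", ]
  expect_equal(sum(dom$count), 2L)  # one compound, two domain incidences
  expect_setequal(dom$target_node, c("reactive", "specific"))
})

test_that("domain-level flow totals bound the classified count", {
  fx <- build_fixture_inventory(seed = 5, n_decoys = 5)
  pp <- preprocess_inventory(fx$records)
  ps <- profile_inventory(pp, core_kb())
  cs <- coverage_summary(ps)
  fl <- sankey_flows(ps)
  dom <- fl[fl$level == "inventory>domain" & fl$target_node != "unclassified", ]
  expect_gte(sum(dom$count), cs$n_classified)
  multi <- any(vapply(ps, function(r)
    length(unique(vapply(r$matches, `[[`, integer(1), "domain_id"))) > 1L, logical(1)))
  if (!multi) expect_equal(sum(dom$count), cs$n_classified)
})

test_that("unclassified compounds flow to a dedicated node", {
  fl <- sankey_flows(list(fake_result("a", list())), "inv")
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$target_node, "unclassified")
})

test_that("exclusive-mode domain proportions sum to one per inventory", {
  res <- list(fake_result("a", list(m_narc)), fake_result("b", list(m_narc)),
              fake_result("c", list(m_spec)), fake_result("d", list()))
  dp <- domain_proportions(list(inv = res))
  expect_equal(sum(dp$proportion), 1, tolerance = 1e-9)
  expect_equal(dp$proportion[dp$category == "narcosis"], 0.5)
  expect_equal(dp$proportion[dp$category == "reactive"], 0)
  expect_equal(dp$proportion[dp$category == "specific"], 0.25)
  expect_equal(dp$proportion[dp$category == "unclassified"], 0.25)
})

test_that("multi-label mode counts compounds, so proportions can exceed one", {
  res <- list(fake_result("a", list(m_narc, m_spec)))
  dp_ex <- domain_proportions(list(inv = res), mode = "exclusive")
  dp_ml <- domain_proportions(list(inv = res), mode = "multi_label")
  expect_equal(sum(dp_ex$proportion), 1, tolerance = 1e-9)
  expect_equal(sum(dp_ml$proportion), 2)  # one compound in two domains
})

test_that("identical inventories give identical proportion rows", {
  res <- list(fake_result("a", list(m_reac)), fake_result("b", list()))
  dp <- domain_proportions(list(x = res, y = res))
  px <- dp[dp$inventory_name == "x", c("category", "proportion")]
  py <- dp[dp$inventory_name == "y", c("category", "proportion")]
  rownames(px) <- rownames(py) <- NULL
  expect_equal(px, py)
  expect_error(domain_proportions(list(bad = list())), "bad")
})
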