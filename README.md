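# aquaprof

Mechanistically grounded structural profiling of aquatic toxicants.

`aquaprof` screens chemical inventories against a tiered knowledge base of
SMARTS structural alerts anchored in molecular initiating events (MIEs),
assigning each compound to a three-domain hierarchy used in aquatic
mode-of-action classification:

* **narcosis** (1) — nonspecific baseline toxicity from membrane
  partitioning, split into nonpolar (1.1) and enhanced (1.2) narcosis;
* **reactive** (2) — intrinsic, nontargeted chemical reactivity
  (electrophilic, nucleophilic, free-radical);
* **specific** (3) — targeted interaction at a defined biomolecule
  (enzyme inhibition, ion channels, cellular-function disruption, ...).

Ten mechanistic groups (Tier 2) and 25 mechanistic subgroups (Tier 3) sit
beneath the domains; each subgroup is anchored in one or more MIEs, each
MIE defined by zero or more structural alerts. An alert is an ordered
conjunction of SMARTS patterns (all must match) with optional exclusion
patterns (any match vetoes), plus a taxonomic-applicability label carried
into every assignment.

Profiling is **two-phase and sequential**: reactive, specific and
enhanced-narcosis alerts are evaluated concurrently first (multi-label —
a compound collects every alert it hits); only compounds with no phase-1
match are tested against the nonpolar-narcosis rules, so a compound with
a reactive, specific or enhanced-narcosis assignment can never also be
labeled a nonpolar narcotic. Compounds matching nothing are reported
unclassified (outside the profiler's domain).

The package also provides structure standardization (canonicalization,
salt stripping, stereochemistry removal, duplicate/inorganic/mixture
rejection with an auditable log), inventory-level reporting
(alert-count histograms, Sankey flow tables, per-inventory domain
proportions), and harmonization of external classification-scheme
outputs (Verhaar/Russom/MechoA-style class tables) onto the broad
domains for concordance analysis. Substructure matching and
canonicalization run on Open Babel via ChemmineOB.

## Worked example

```r
library(aquaprof)

kb <- core_kb()
kb
#> Alert knowledge base: aquaprof core alert set
#>   version: 0.9
#>   3 domains, 10 groups, 25 subgroups, 20 MIEs, 34 alerts

inv <- data.frame(
  record_id = c("parathion", "methyl-acrylate", "hexane", "glyphosate-salt"),
  smiles = c("CCOP(=S)(OCC)Oc1ccc([N+](=O)[O-])cc1",
             "C=CC(=O)OC", "CCCCCC", "OC(=O)CNCP(=O)(O)O.[Na+]"))
pp <- preprocess_inventory(inv)
ps <- profile_inventory(pp, kb)
ps[[1]]
#> <parathion> CCOP(=S)(Oc1ccc(cc1)[N+](=O)[O-])OCC: classified (phase 1)
#>   1.2.1-SA03   mononitro aromatic [narcosis 1.2.1 / all taxa and species]
#>   3.1.1-SA01   organophosphorus triester [specific 3.1.1 / Metazoa]
ps[[3]]
#> <hexane> CCCCCC: classified (phase 2)
#>   1.1.1-SA01   saturated aliphatic hydrocarbon [narcosis 1.1.1 / all taxa and species]

coverage_summary(ps)
#> Coverage: 4 compounds, 4 classified, 0 unclassified (0.0%)
#> Alerts per compound:  1: 2, 2: 2, >=3: 0
#> By domain:  narcosis: 3, specific: 2, reactive: 1
```

Parathion is multi-labeled in phase 1 (its nitrophenyl ring carries the
aromatic-nitro narcosis rule alongside the organophosphate
acetylcholinesterase alert, the latter restricted to Metazoa); methyl
acrylate hits both the ester-narcosis and Michael-acceptor rules; hexane
reaches phase 2 and is assigned nonpolar narcosis; the glyphosate sodium
salt is stripped to its parent acid and matches the EPSP-synthase alert
under subgroup 3.3.1.

A knowledge-base overview in the published table layout:

```r
s <- kb_summary(kb)
s[s$subgroup_id == "3.3.1", c("subgroup_id", "subgroup_name", "n_mie", "n_sa")]
#>  subgroup_id                      subgroup_name n_mie n_sa
#>        3.3.1 amino acid biosynthesis disruption     3    6
```

## Command line

A thin CLI over the same functions ships in `inst/scripts/aquaprof.R`:

```sh
Rscript inst/scripts/aquaprof.R validate-kb --kb inst/extdata/core_kb.yaml
Rscript inst/scripts/aquaprof.R profile --input inventory.smi \
    --output results.csv --summary summary.json
Rscript inst/scripts/aquaprof.R sankey --results results.csv --output flows.csv
```

Subcommands: `validate-kb`, `kb-summary`, `prep`, `profile`, `summarize`,
`sankey`, `compare`, `fixtures`.

## Knowledge-base format

KBs are YAML (canonical) or JSON with top-level keys `metadata`,
`domains`, `groups`, `subgroups`, `mies`, `alerts`; the schema is
documented in `inst/extdata/kb-schema.json`. The shipped core KB
(`inst/extdata/core_kb.yaml`) carries the full 25-subgroup skeleton and
34 alerts spanning all three domains, each with embedded
positive/negative example structures that `validate_kb()` re-runs. The
format hosts the full published 183-alert set unchanged if you supply it.

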