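---
title: "Mechanistic structural profiling of aquatic toxicants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic structural profiling of aquatic toxicants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaprof)
```

## The classification problem

Most chemicals in industrial use lack the experimental data needed to
assess their hazard to aquatic species. A long-standing remedy is to
assign a *mode or mechanism of toxic action* from structure alone:
baseline narcosis for inert, membrane-partitioning chemicals; reactive
toxicity for intrinsic electrophiles and radical generators; and specific
toxicity for compounds that engage a defined biomolecular target.
Second-generation classification schemes anchor these assignments in
*molecular initiating events* (MIEs) — the first chemical–biological
interaction of an adverse outcome pathway — rather than in chemical class
membership alone.

`aquaprof` implements such a scheme as a screening tool. The hierarchy has
three tiers above the MIE level:

* **Tier 1 — domains**: narcosis (1), reactive (2), specific (3);
* **Tier 2 — ten mechanistic groups** (e.g., 1.2 enhanced narcosis, 2.1
  electrophilic, 3.1 enzyme inhibition);
* **Tier 3 — 25 mechanistic subgroups** (e.g., 2.1.1 soft electrophiles,
  3.3.1 amino acid biosynthesis disruption);

each subgroup owns one or more MIEs, and each MIE owns zero or more
*structural alerts* — SMARTS substructure patterns that flag
participation in that MIE. Every assignment carries its full tier lineage
and a taxonomic-applicability label (from "all taxa and species" down to
single species), because many specific mechanisms are meaningful only for
particular clades (photosystem II inhibition for plants and algae,
acetylcholinesterase inhibition for metazoans).

## Alert encoding

An alert is an ordered *conjunction* of one or more SMARTS patterns —
every pattern must embed at least once in the molecule — plus an optional
set of *exclusion* patterns, any match of which vetoes the alert. Single
patterns suffice for most functional-group chemistry; stepwise
multi-pattern sequences are needed where a mechanism is defined by the
co-occurrence of independent features, the canonical case being
surfactants (a quaternary ammonium head group *and* a long hydrophobic
tail, neither sufficient alone). Exclusions express the "but not"
clauses that keep broad narcosis rules from swallowing activated
chemistry: the phenol rule, for instance, vetoes structures carrying
carbonyl, sulfonyl or phosphorus functionality, which belong to more
specific alerts.

Duplicate embeddings of one pattern count once; matching is a set
membership question, not an occurrence count. When atom provenance is
requested, the atom indices of the first embedding of the first pattern
in the sequence are reported — a reporting convenience only, with no
bearing on classification.

All SMARTS in the shipped knowledge base are authored and validated
against **Open Babel's aromaticity and valence model** (the backend used
for all matching and canonicalization, via ChemmineOB). A KB written for
a different aromaticity model (e.g., RDKit's) may perceive rings
differently; the KB metadata records the intended model for this reason.

## The two-phase sequential workflow

Profiling is *multi-label within a phase* and *exclusive across phases*:

1. **Phase 1** evaluates, concurrently, every alert from the reactive and
   specific domains together with mechanistic group 1.2 (enhanced
   narcosis). A compound collects *every* alert it matches — the tool's
   purpose is to surface all MIEs a structure could engage, not to force a
   single verdict.
2. **Phase 2** is reached only by compounds with no phase-1 match, and
   applies the nonpolar narcosis rules (group 1.1). Baseline narcosis is
   the default expectation for any chemical; reporting it alongside a
   reactive or specific assignment would add no information, so a
   compound with any phase-1 assignment can never also be labeled a
   nonpolar narcotic.
3. Compounds unmatched in both phases are **unclassified** — outside the
   profiler's domain, not demonstrated inert.

Within a phase, evaluation order is irrelevant: all alerts are evaluated
(no short-circuiting), and the result is a set. A compound whose only
candidate alerts were vetoed by exclusions proceeds to phase 2 like any
other unmatched compound.

## Structure standardization

Raw inventory records are standardized before profiling:

* SMILES are parsed and **canonicalized** with Open Babel;
* **stereochemistry is deleted** (alerts are constitutional, not
  stereochemical); deletion is lexical — `@`, `/` and `\` occur in
  SMILES only as stereo marks — followed by re-canonicalization;
* **salts are stripped**: among carbon-containing fragments the one with
  the most heavy atoms is kept, ties broken by higher molecular weight,
  then by lexicographically smallest canonical SMILES. The tie-break
  cascade makes stripping deterministic for symmetric salts;
* records with **no carbon-containing fragment are rejected** as
  inorganic;
* if two or more organic fragments remain and the largest accounts for no
  more than 70% of their heavy atoms, the record is rejected as a
  **mixture**. The threshold is a package decision (configurable via
  `mixture_threshold`): true salts and solvates almost always pair a
  dominant parent with small counterions, while co-formulations split
  their atoms more evenly. No criterion can be read off a SMILES line
  with certainty, so the rule is documented rather than claimed exact;
* **duplicates** (identical parent SMILES after the above) keep their
  first occurrence; later copies are logged as duplicates. Input order
  therefore decides which *record* survives but never which *structures*
  are retained;
* **polymers** cannot be recognized from a SMILES line at all; records
  flagged polymeric via the optional `polymer_flag` column are rejected
  as `undefined_structure`, all others pass through.

Deliberately *not* done: charge neutralization and tautomer
canonicalization. Both would silently rewrite the chemistry the alerts
are matched against; profiling operates on the stripped parent as-is, and
ionizable handling is pushed into the alerts themselves (e.g., the nitro
group is matched in both its charge-separated and pentavalent
depictions).

Every input record ends up in exactly one of the standardized set or the
rejection log — the partition is asserted in the tests, and
re-standardizing any emitted parent is the identity (idempotence).

## The shipped core knowledge base

The package ships the complete 3/10/25 tier skeleton and a core set of 34
alerts across 20 MIEs, spanning all three domains: six Verhaar-derived
nonpolar narcosis rules (saturated hydrocarbons, aromatics, halo-variants,
alcohols, ethers), polar narcosis rules (phenols, anilines,
mononitroaromatics, the stepwise quaternary-ammonium surfactant
sequence), alkyl amine and carboxylic-ester enhanced narcosis, soft
electrophiles (Michael acceptors, activated nitriles, alpha-halocarbonyls,
isothiocyanates), hard electrophiles (aldehydes, epoxides), pre-reactive
and radical mechanisms (vicinal dihaloalkanes, hydroperoxides, quinones,
nitrofurans, polyhalomethanes), acetylcholinesterase inhibition
(organophosphorus triesters, carbamate esters), photosystem II inhibition
(triazines, phenylureas), sodium-channel modulation (DDT-type
diarylmethanes), and the six amino-acid-biosynthesis alerts — four
acetolactate-synthase modulator forms (triazolopyrimidine sulfonanilides,
imidazolinones, sulfonylureas, pyrimidinylbenzoates), one EPSP-synthase
and one glutamine-synthetase alert.

The full published rule set for this scheme comprises 183 alerts; the
core KB is a representative, self-validating subset, and the file format
(YAML or JSON, schema in `inst/extdata/kb-schema.json`) loads a full user
supplied set unchanged. Alert ids are `<subgroup>-SA<nn>`, so lineage is
derivable from the id alone and ids are stable under KB edits. Each MIE
has exactly one parent subgroup (the hierarchy is a tree). A
`property_constraints` field is reserved in the schema for numeric bounds
(e.g., log P windows inherited from narcosis rule sets) but the core KB
uses purely structural conditions — structural matching is this package's
contribution, and mixing silent property filters into alerts would
complicate the oracle story for no desk-scale gain.

Every alert embeds positive and negative example structures;
`validate_kb()` re-runs them all (210 checks for the core KB), so the KB
carries its own oracle suite. Multi-label cross-hits among the examples
are intentional chemistry, not noise: methyl acrylate is both an ester
narcotic and a Michael acceptor; quinones are Michael acceptors as well
as redox cyclers; parathion's nitrophenyl ring carries the
aromatic-nitro rule alongside the organophosphate alert.

## Aggregation choices

`coverage_summary()` reports the alerts-per-compound distribution both in
full and in the conventional 1 / 2 / ≥3 binning. For an empty result set
the unclassified percentage is reported as 0 with an explicit `empty`
flag rather than as `NaN` — degenerate inputs should flow through
downstream tabulation, not crash it.

`sankey_flows()` counts compound-category *incidences*: a compound
matching two groups contributes one unit to each group edge, so totals at
lower tiers may exceed those above — the expected signature of
multi-label classification, preserved rather than normalized away.

`domain_proportions()` must decide how a multi-domain compound is
apportioned, which the scheme itself does not specify. The default
("exclusive" mode) counts compound-domain incidences so each
inventory's bar sums to 1; `multi_label` mode divides by compound count
instead, so bars can exceed 1. Both are provided because either reading
of a published per-domain proportion is defensible; the mode is an
explicit argument, never a silent default changed between releases.

## Interscheme harmonization

External scheme outputs (Verhaar, Russom, MechoA classes) are mapped to
the four-value vocabulary {narcotic, reactive, specific,
unclassified_or_out_of_domain} via a user-replaceable CSV. Three anchor
rows are fixed by the published cross-scheme correspondence (Verhaar 3 →
reactive, Russom 6 → specific, MechoA 1.3 → narcotic); the remaining
default rows extend those anchors by each scheme's own class semantics
and are expected to be overridden by a full user-supplied mapping.
Unknown labels are flagged and reported, never dropped; harmonization is
idempotent on already-harmonized labels. Because the Russom scheme
classifies unmatched compounds as narcotic by default, its coverage is
not comparable through the "not unclassified" definition; the optional
`in_domain` column carries applicability-domain flags through for
schemes that provide them, and `concordance()` reports raw coverage per
scheme alongside the 4×4 label contingency (multi-assignment records
contribute one unit per label pair).

## The fixture generator, and what it does not show

`build_fixture_inventory()` assembles the desk-scale study inputs: 37
curated exemplars covering every core-KB alert (with hand-derived
*complete* expected alert sets, including the multi-label and
phase-suppression cases), three preprocessing probes (a salt, an
inorganic, a respelled duplicate), and seeded decoys drawn from
chemistry provably inert under every reactive and specific rule — linear
alkanes (C7–C12) and linear primary alcohols (C5–C12), whose expected
label (nonpolar narcosis, phase 2) is derivable without ambiguity. Decoy
chain lengths deliberately avoid the curated alkane/alcohol exemplars so
decoys never collide with curated parents during deduplication.

This emulates the *logic* of inventory screening — multi-label
accumulation, phase suppression, preprocessing rejections — at a size
where every expected outcome can be enumerated by hand. It does not
emulate real inventory composition: no pharmaceutical-like polycycles, no
organometallics, no structures near the boundary of an alert's intended
scope, and a classification rate far above what a 34-alert core set
achieves on real inventories. Passing tests demonstrate that the workflow
computes the scheme faithfully, not that the core KB covers chemical
space.

Test problem sizes are chosen for exhaustiveness per structure rather
than scale: the sequential-logic property runs ~240 profiles across five
seeded, shuffled fixture inventories; oracle-equivalence checks every
fixture molecule against a flat brute-force evaluation of all KB alerts
(through a separate SDF-based call path) followed by post-hoc application
of the phase rule.

## Known limitations

* The core KB is a subset; unclassified results on real inventories are
  dominated by uncovered chemistry, exactly as for the full published
  set, whose narcosis rules are themselves known to exclude eligible
  phenols, nitriles, sulfur compounds and some aryl halides.
* SMARTS semantics are toolkit-coupled. The shipped patterns are
  validated under Open Babel only.
* Taxonomic applicability is an open label vocabulary, not an ontology;
  labels are reported verbatim.
* Enhanced-narcosis (group 1.2) matches are reported exactly as any other
  phase-1 assignment; no downstream summary suppresses or privileges them.
* Potency, consensus mechanism calls and applicability-domain modeling
  are out of scope by design.
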