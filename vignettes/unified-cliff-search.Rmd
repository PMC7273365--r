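---
title: "A unified search for dual-site, isomer and privileged-substructure activity cliffs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A unified search for dual-site, isomer and privileged-substructure activity cliffs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitecliffs)
```

## The problem

An activity cliff (AC) is a pair of structural analogs with a large potency
difference against a shared target. Classic cliff analysis rests on matched
molecular pairs (MMPs): two compounds differing by a single-site chemical
change. `sitecliffs` targets the complementary situation in which the two
analogs differ at *two* substitution sites of a common core. Three
categories are detected in one pass with consistent criteria:

* **dual-site ACs (ds-ACs)**: different substituents at different core
  positions;
* **isomer ACs (iso-ACs)**: the same substituent at two different core
  positions, making the partners constitutional isomers. Every iso-AC is by
  definition also a ds-AC. Chirality cliffs (identical constitution,
  different stereocenters) are a different phenomenon and are out of scope;
* **privileged-substructure ACs (PS-ACs)**: cliffs of either kind whose
  shared core contains a pattern from a library of recurrent,
  family-directed core structures.

Because the same fragmentation, pairing and potency criteria drive all
three categories, their overlap is well defined: category counts are
additive (iso + non-iso ds = total, PS + non-PS = total), and the package
asserts these identities on every run.

## Model and assumptions

**Potency.** Only assay-independent equilibrium constants are used. Each
measurement is converted to molar and expressed as pKi = −log₁₀ Ki [M]. A
100-fold potency ratio is then ΔpKi = 2, and the cliff criterion
"at least 100-fold" becomes |pKi₁ − pKi₂| ≥ 2, *inclusive*. Floating-point
arithmetic gets a 10⁻⁹ tolerance at the boundary so a computed difference
of exactly 2.0 qualifies.

**High-confidence data.** Records must describe a direct interaction
(assay relationship type `D`) with a human target at the highest assay
confidence (score 9), measurement type `Ki` with an exact `=` relation.
The organism value is configurable (`"Homo sapiens"` by default, matching
ChEMBL exports).

**Replicate aggregation.** Where several measurements exist for one
(structure, target), their pKi values are averaged arithmetically, and the
entry is discarded when the spread (max − min) exceeds 1 log unit. The
rationale: a ≥100-fold cliff should never be attributable to measurement
scatter; a 1-log-unit cap keeps worst-case aggregate error well below the
2-log-unit criterion. Both the rule and the cap are exposed as
configuration (`pki_spread_max`).

**Units.** `nM`, `uM`/`µM` and `M` are accepted case-insensitively (plus
`mM`/`pM` internally); anything else is rejected row-wise when a whitelist
is passed to the reader, or raises an error naming the unit during
aggregation.

## Fragmentation and position classes

Every acyclic single bond between two heavy atoms is cut in turn — ring
bonds are never cut, bonds to hydrogen do not exist in the heavy-atom
graph, and each cut therefore yields exactly two connected fragments. The
larger fragment is the core; the cut qualifies when

* core heavy atoms ≥ 2 × substituent heavy atoms, and
* substituent heavy atoms ≤ 13,

both inclusive. The core's cut point is capped with hydrogen (R → H) and
the core re-canonicalized; the substituent keeps an explicit `*` attachment
label, so attachment regiochemistry within the substituent is part of its
identity. "Exocyclic single bond" deliberately includes chain–chain bonds:
cutting ethylbenzene's terminal bond produces the toluene core with a
methyl substituent, which is required for cores that themselves carry the
complementary substituent.

"Different sites" is decided on *symmetry classes*, not raw atom indices:
a position is labeled by the canonical SMILES of the core with a dummy
atom attached at that position, and positions with equal labels are one
class. Two positions get the same label exactly when an automorphism of
the capped core maps one onto the other, so the class is independent of
input atom numbering; integer class ids are ranks of the sorted labels.
This is why benzene-core analogs can never form a dual-site pair — all six
positions are one class — while naphthalene supports them with three
distinct CH classes. The test suite cross-checks this labeling against
exact graph-automorphism orbits computed by an independent route
(igraph VF2 isomorphism on colored, edge-subdivided graphs).

**Stereochemistry.** Standardized compound SMILES preserve stereo
annotations, but fragment extraction runs through coordinate-free
connection tables, so cores and substituents are compared
stereo-agnostically. Cliffs between stereoisomeric analogs of the same
constitution are consequently not separated; for the two-site analog
relationships targeted here this is a deliberate simplification, and the
synthetic validation uses achiral chemistry throughout.

## Analog pairs, deduplication and cliffs

Compounds sharing a capped core and a target form an analog set (sets with
fewer than two compounds are dropped). All unordered pairs with distinct
compounds, distinct position classes and a substituent size difference of
at most 8 heavy atoms qualify; equal-class pairs are classic single-site
analogs and are excluded. A compound pair can qualify through several
alternative cores; it is reported once per target, keeping the
decomposition with the largest core (ties: lexicographically smallest core
SMILES, then `iso` before `ds`) and listing all supporting cores in an
evidence column — pair and cliff counts therefore count compound pairs,
never decompositions.

Pairs with |ΔpKi| ≥ 2 are cliffs. PS annotation matches the library
against the shared capped core by default, which guarantees the pattern is
present in *both* cliff partners; `either`/`both` scopes matching the full
molecules are available as configuration. When several patterns match, the
largest by heavy-atom count is reported and all matches are recorded.

For each ds-AC the analog set is searched for repositioned isomers: the
potent compound's substituent at the weak compound's position class, and
vice versa. Found isomers must be structures distinct from both cliff
compounds — for an iso-AC the would-be isomers coincide with the cliff
partners, so iso-ACs are never extended. Extension status is `full`
(both found), `partial` (one) or `none`, and each extension compound
carries its own pKi so site-specific potency contributions can be read
off directly.

## The privileged-substructure library

Patterns are plain inputs (`NAME<TAB>SMARTS`, `#` comments); the package
never mines them. `screen_ps_frequency()` implements the frequency
criterion — keep patterns contained in at least `min_count` (default 100)
*unique standardized structures* — and is meant to run against a large
reference compound collection; `run_pipeline()` therefore does not screen
by default, since a cliff dataset is usually far smaller than the
collection the threshold refers to. The shipped
`inst/extdata/ps_library_starter.tsv` is a synthetic stand-in of sixteen
well-known privileged cores (indole, quinoline, benzimidazole, biphenyl,
arylpiperazine, …), intended to make the pipeline runnable and testable
out of the box; production analyses should substitute a curated library.

## The synthetic generator and what it shows

`generate_fixture()` assembles analog series literally: a scaffold
template contributes one slot string per substitution site (two
topologically distinct sites on naphthalene, indole or quinoline), and a
substituent is a SMILES prefix attaching through its last atom. Potencies
follow a planted model: a baseline pKi (default 6.0) per analog set, a
cliff offset (default 3.0) added to planted potent compounds, and uniform
noise of amplitude < 0.5 log units — so planted cliffs always clear the
2-log criterion and unplanted pairs never reach it. Defaults were chosen
once as typical of medicinal-chemistry analog series (nanomolar-to-
micromolar Ki range, a few-fold replicate scatter) and are not tuned to
test outcomes.

The expected pairs, cliffs, categories and extension statuses are computed
*combinatorially from the design table* — never by the pipeline under
test — which makes the generator an anti-circular oracle for end-to-end
validation. The construction (single substituent per compound, linear
prefix substituents, rigid scaffolds) guarantees that two fixture
compounds share alternative cores only in configurations the truth
enumeration accounts for; `corrupt_fixture()` additionally injects rows
(censored relations, low confidence scores, unconvertible units, salt
forms) that a correct pipeline must remove without changing its output.

Passing these tests shows the search logic is exact under its own
assumptions. It does *not* show robustness to features real ChEMBL data
has and the generator lacks: multi-substituent analogs, flexible or fused
ring systems cut in several places, stereochemistry, tautomers, or the
heavy-tailed size distribution of real analog series. The
fragmenter-versus-brute-force test on random molecules covers part of that
gap structurally, not pharmacologically.

## Numerical and design choices

* Cliff threshold: inclusive, with a 10⁻⁹ pKi tolerance; lowering
  `min_fold` can only grow the cliff set (tested monotonicity).
* Replicate aggregation: arithmetic mean of pKi; spread cap 1.0 log unit.
* Compounds identical after standardization are merged; the
  lexicographically smallest compound id represents the structure.
* Deduplication tie-breaks (core size, then SMILES, then `iso` over `ds`,
  then substituent order) are total, so repeated runs and atom-renumbered
  inputs produce byte-identical output tables; rows are sorted by target
  and compound ids before `ac_id` assignment.
* Degenerate inputs: empty tables flow through with zero counts; molecules
  without cuttable bonds (e.g. benzene) simply produce no fragmentations;
  single-atom structures cannot match multi-atom patterns and are treated
  as non-matching.
* Validation problem sizes: end-to-end truth recovery over 20 seeded
  fixture designs (up to ~60 compounds, 2 targets each), fragmenter-oracle
  equivalence over 200 random molecules of ≤ 20 heavy atoms, and exact
  boundary assertions at every threshold (ΔpKi 2.00/1.99, substituent
  13/14, ratio 2:1, size difference 8/9, frequency 100/99).

## Limitations

* Core matching is stereo-agnostic (see above).
* Aromaticity and canonicalization follow OpenBabel's perception model;
  a different toolkit may split or merge rare position classes.
* The frequency screen needs a reference compound collection to be
  meaningful; the starter pattern file is a stand-in, not a curated
  privileged-substructure set.
* Only single-cut (two-fragment) decompositions are enumerated; pairs
  differing at more than two sites, single-site MMP cliffs and cliffs
  against confirmed-inactive analogs are out of scope.

## A complete run

```{r example, eval = FALSE}
spec <- fixture_spec(scaffolds = c("naphthalene", "indole"),
                     n_targets = 2, seed = 11)
fx <- generate_fixture(spec)
cfg <- run_config(ps_library = system.file("extdata",
                                           "ps_library_starter.tsv",
                                           package = "sitecliffs"))
res <- run_pipeline(cfg, activity = fx$activity)
res$summary
write_cliff_table(res$cliffs, "activity_cliffs.tsv")
```
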