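# sitecliffs

Activity cliffs are pairs of structurally analogous compounds that act on
the same target with a large potency difference; they mark the steepest,
most informative regions of a structure-activity relationship (SAR).
`sitecliffs` implements a unified search for three related cliff categories
that go beyond the classic single-site definition:

- **dual-site cliffs (ds-ACs)** — the two analogs carry *different*
  substituents at *different* positions of a shared core;
- **isomer cliffs (iso-ACs)** — the *same* substituent sits at two
  different core positions, so the analogs are constitutional isomers
  (a special case of ds-ACs);
- **privileged-substructure cliffs (PS-ACs)** — cliffs of either kind whose
  shared core contains a recurrent, family-directed core structure
  ("privileged substructure") from a user-supplied pattern library.

The package is aimed at computational medicinal chemists who want to mine a
compound–activity table (e.g. a ChEMBL activity export) for these cliffs,
and at method developers who need a fully testable reference
implementation: a synthetic analog-series generator with combinatorially
derived ground truth ships as first-class, tested code.

## Method

Given per-compound equilibrium constants (Ki) against protein targets, the
search proceeds in five stages:

1. **Ingest.** High-confidence filtering (human targets, direct-interaction
   assays at top confidence, `Ki` measurements with an exact `=` relation),
   structure standardization (salt stripping, charge neutralization,
   canonicalization), and aggregation to one potency per compound and
   target: pKi = −log₁₀ Ki [M], averaged over replicates; compounds whose
   replicate pKi values spread over more than 1 log unit are discarded.
2. **Fragmentation.** Every exocyclic (acyclic) single bond is cut in turn,
   yielding a core and a substituent. A cut qualifies if the core has at
   least twice as many heavy atoms as the substituent and the substituent
   has at most 13 heavy atoms. The cut point on the core is capped with
   hydrogen (R → H); the attachment position is labeled by its symmetry
   class in the capped core, so topologically equivalent positions compare
   equal.
3. **Analog pairs.** Compounds active against the same target and sharing a
   capped core form an analog set. Within a set, every unordered compound
   pair whose substituents sit at two *different* position classes — with a
   substituent size difference of at most 8 heavy atoms — is an analog
   pair: `iso` if the substituents are identical, `ds` otherwise. A pair
   qualifying through several cores is counted once (largest core kept).
4. **Cliff calling.** A pair is an activity cliff when |ΔpKi| ≥ 2, i.e. an
   at-least-100-fold potency difference (inclusive). Cliffs whose core
   contains a library pattern are additionally PS-ACs.
5. **Extension.** For each ds-AC, the analog set is searched for the two
   repositioned isomers — the potent compound's substituent at the weak
   compound's site and vice versa. With both found the cliff extends to a
   four-compound data structure that exposes how much each substitution
   site contributes to the cliff.

## Worked example

Plant one dual-site cliff in a tiny naphthalene series and recover it:

```r
library(sitecliffs)

spec <- fixture_spec(
  scaffolds = "naphthalene",
  substituents = c("methyl", "chloro"),
  noise_amp = 0, cliff_offset = 3,
  potent_when = function(site, sub) site == "s1" && sub == "methyl")
fx <- generate_fixture(spec)
res <- run_pipeline(run_config(), activity = fx$activity)
res$summary
#>            n_records_read        n_records_rejected n_records_high_confidence
#>                         4                         0                         4
#>               n_compounds                 n_targets             n_analog_sets
#>                         4                         1                         1
#>            n_analog_pairs                     n_acs                  n_ds_acs
#>                         4                         2                         2
#>                 n_iso_acs                  n_ps_acs               n_nonps_acs
#>                         1                         0                         2
#>                n_ext_full             n_ext_partial                n_ext_none
#>                         1                         0                         1
```

The four compounds (1-/2-methyl- and 1-/2-chloronaphthalene, with
1-methylnaphthalene planted at pKi 9 versus baseline 6) form four cross-site
analog pairs and two cliffs:

```r
format_cliff_table(res$cliffs)[, c("ac_id", "categories", "cpd1_id",
                                   "cpd1_pki", "cpd2_pki", "delta_pki",
                                   "extension_status")]
#>   ac_id   categories cpd1_id cpd1_pki cpd2_pki delta_pki extension_status
#> 1 AC00001 ds;iso     CPD0001 9.00     6.00     3.00      none
#> 2 AC00002 ds         CPD0001 9.00     6.00     3.00      full
```

`AC00001` is the isomer cliff (methyl moved from the 1- to the 2-position;
its would-be extension isomers are the cliff compounds themselves, so it
cannot be extended). `AC00002` is the dual-site cliff methyl@1 vs chloro@2;
both repositioned isomers (methyl@2, chloro@1) exist in the series, so its
extension is `full`. `write_cliff_table()` writes the full deposition-style
TSV with structures, potencies, core, substituents, position classes and
the extension compound ids.

For shell use, `inst/cli/sitecliffs.R` exposes the stages as subcommands
(`run`, `simulate`, `filter`, `fragment`, `pairs`, `cliffs`, `extend`,
`ps-screen`).

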