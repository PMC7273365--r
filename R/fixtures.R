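# Synthetic analog series with planted cliffs and combinatorial ground truth.
#
# Compounds are assembled literally: a scaffold template carries one slot
# string per substitution site ("{R}..." prefix form) and a substituent is a
# SMILES prefix attaching through its last written atom. Because molecules
# are built this way, the (core, site, substituent) decomposition of every
# compound is known by construction, and the expected pairs, cliffs and
# extension statuses can be enumerated directly from the design table
# without running the pipeline: the anti-circularity oracle for end-to-end
# tests.

#' Built-in fixture scaffolds
#'
#' Each scaffold offers two topologically distinct substitution sites as
#' `{R}`-slot template strings; `has_ps` flags scaffolds whose core contains a
#' pattern from the starter privileged-substructure library shipped with the
#' package.
#'
#' @return named list of scaffolds (`name`, `sites`, `heavy`, `has_ps`).
#' @export
fixture_scaffolds <- function() {
  list(
    naphthalene = list(
      name = "naphthalene",
      sites = c(s1 = "{R}c1cccc2ccccc12",   # 1-position
                s2 = "{R}c1ccc2ccccc2c1"),  # 2-position
      heavy = 10L, has_ps = FALSE),
    indole = list(
      name = "indole",
      sites = c(s3 = "{R}c1c[nH]c2ccccc12",    # 3-position
                s5 = "{R}c1ccc2[nH]ccc2c1"),   # 5-position
      heavy = 9L, has_ps = TRUE),
    quinoline = list(
      name = "quinoline",
      sites = c(s2 = "{R}c1ccc2ccccc2n1",   # 2-position
                s3 = "{R}c1cnc2ccccc2c1"),  # 3-position
      heavy = 10L, has_ps = TRUE))
}

#' Built-in fixture substituents
#'
#' SMILES prefixes attaching through their last written atom, with heavy-atom
#' counts. All entries canonicalize to distinct attachment-labeled fragments.
#'
#' @return tibble with `sub`, `prefix`, `heavy`.
#' @export
fixture_substituents <- function() {
  tibble::tibble(
    sub = c("methyl", "ethyl", "propyl", "chloro", "fluoro", "bromo",
            "hydroxy", "amino", "methoxy", "cyano", "trifluoromethyl",
            "acetyl"),
    prefix = c("C", "CC", "CCC", "Cl", "F", "Br", "O", "N", "CO", "N#C",
               "FC(F)(F)", "CC(=O)"),
    heavy = c(1L, 2L, 3L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 4L, 3L))
}

#' Specify a synthetic fixture
#'
#' @param scaffolds names from [fixture_scaffolds()].
#' @param substituents names from [fixture_substituents()].
#' @param n_targets number of target proteins.
#' @param base_pki baseline potency of an analog set, in pKi units.
#' @param cliff_offset potency boost of planted potent compounds (log units).
#'   Either at least `2 + 2 * noise_amp`, so every planted cliff clears the
#'   100-fold criterion and unplanted pairs never do, or (for negative
#'   controls) small enough that no pair can reach it.
#' @param noise_amp half-width of the uniform pKi noise (< 0.5 log units).
#' @param p_potent probability that a compound is planted as potent.
#' @param potent_when optional predicate `function(site, sub)` returning
#'   `TRUE` for combinations planted as potent; overrides `p_potent` for
#'   fully deterministic designs.
#' @param fill probability that a (scaffold, site, substituent) combination
#'   is included for a target; 1 gives the full matrix (all cliffs fully
#'   extendable where isomer slots are distinct compounds).
#' @param n_replicates measurement rows emitted per compound and target.
#' @param seed RNG seed; generation is reproducible for a fixed seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(scaffolds = c("naphthalene", "indole"),
                         substituents = c("methyl", "ethyl", "chloro",
                                          "methoxy"),
                         n_targets = 1L, base_pki = 6.0, cliff_offset = 3.0,
                         noise_amp = 0.3, p_potent = 0.35,
                         potent_when = NULL, fill = 1.0,
                         n_replicates = 1L, seed = 1L) {
  all_sc <- fixture_scaffolds()
  all_su <- fixture_substituents()
  stopifnot(all(scaffolds %in% names(all_sc)),
            all(substituents %in% all_su$sub),
            noise_amp >= 0, noise_amp < 0.5,
            cliff_offset >= 2 + 2 * noise_amp ||
              cliff_offset + 2 * noise_amp < 2,
            n_targets >= 1, fill > 0, fill <= 1, n_replicates >= 1)
  structure(list(scaffolds = all_sc[scaffolds],
                 substituents = all_su[all_su$sub %in% substituents, ],
                 n_targets = as.integer(n_targets), base_pki = base_pki,
                 cliff_offset = cliff_offset, noise_amp = noise_amp,
                 p_potent = p_potent, potent_when = potent_when, fill = fill,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

assemble_smiles <- function(slot, prefix) {
  sub("{R}", prefix, slot, fixed = TRUE)
}

# Design table: one row per (target, scaffold, site, substituent) included.
fixture_design <- function(spec) {
  sc <- spec$scaffolds
  su <- spec$substituents
  combos <- dplyr::bind_rows(lapply(sc, function(s) {
    tibble::tibble(scaffold = s$name, site = names(s$sites),
                   slot = unname(s$sites), has_ps = s$has_ps,
                   scaffold_heavy = s$heavy)
  }))
  combos <- dplyr::cross_join(combos, su)
  combos$smiles <- mapply(assemble_smiles, combos$slot, combos$prefix,
                          USE.NAMES = FALSE)
  combos$compound_id <- sprintf("CPD%04d", seq_len(nrow(combos)))
  design <- dplyr::bind_rows(lapply(seq_len(spec$n_targets), function(t) {
    d <- combos
    d$target_id <- sprintf("T%03d", t)
    d
  }))
  design$keep <- stats::runif(nrow(design)) <= spec$fill
  design <- design[design$keep, , drop = FALSE]
  design$potent <- if (is.null(spec$potent_when)) {
    stats::rbinom(nrow(design), 1L, spec$p_potent) == 1L
  } else {
    mapply(spec$potent_when, design$site, design$sub, USE.NAMES = FALSE)
  }
  design$pki <- spec$base_pki +
    ifelse(design$potent, spec$cliff_offset, 0) +
    stats::runif(nrow(design), -spec$noise_amp, spec$noise_amp)
  design$keep <- NULL
  design
}

# Independent brute-force truth: enumerate all cross-site pairs and apply
# the cliff/extension rules directly on the design table.
fixture_truth <- function(design) {
  empty_pairs <- tibble::tibble(target_id = character(), cpd_a = character(),
                                cpd_b = character(), pair_type = character(),
                                size_diff = integer())
  empty_cliffs <- tibble::tibble(target_id = character(), cpd_a = character(),
                                 cpd_b = character(), pair_type = character(),
                                 delta_pki = numeric(), is_ps = logical(),
                                 extension_status = character())
  pair_rows <- list()
  cliff_rows <- list()
  groups <- split(design, list(design$target_id, design$scaffold),
                  drop = TRUE)
  for (g in groups) {
    n <- nrow(g)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (g$site[i] == g$site[j]) next
        if (g$compound_id[i] == g$compound_id[j]) next
        if (abs(g$heavy[i] - g$heavy[j]) > 8L) next
        ca <- min(g$compound_id[i], g$compound_id[j])
        cb <- max(g$compound_id[i], g$compound_id[j])
        type <- if (g$sub[i] == g$sub[j]) "iso" else "ds"
        pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
          target_id = g$target_id[1], cpd_a = ca, cpd_b = cb,
          pair_type = type,
          size_diff = abs(g$heavy[i] - g$heavy[j]))
        delta <- abs(g$pki[i] - g$pki[j])
        if (delta >= 2 - 1e-9) {
          p <- if (g$pki[i] >= g$pki[j]) i else j
          w <- if (p == i) j else i
          # repositioned isomers: potent sub at weak site and vice versa,
          # as distinct structures from both cliff compounds
          iso_p <- g$site == g$site[w] & g$sub == g$sub[p] &
            !(g$smiles %in% c(g$smiles[i], g$smiles[j]))
          iso_w <- g$site == g$site[p] & g$sub == g$sub[w] &
            !(g$smiles %in% c(g$smiles[i], g$smiles[j]))
          k <- any(iso_p) + any(iso_w)
          cliff_rows[[length(cliff_rows) + 1L]] <- tibble::tibble(
            target_id = g$target_id[1], cpd_a = ca, cpd_b = cb,
            pair_type = type, delta_pki = delta, is_ps = g$has_ps[1],
            extension_status = c("none", "partial", "full")[k + 1L])
        }
      }
    }
  }
  list(pairs = if (length(pair_rows)) dplyr::bind_rows(pair_rows)
               else empty_pairs,
       cliffs = if (length(cliff_rows)) dplyr::bind_rows(cliff_rows)
                else empty_cliffs)
}

#' Generate a synthetic activity table with ground truth
#'
#' Emits a ChEMBL-dialect activity table (all rows passing the
#' high-confidence filters, Ki in nM) together with a truth object computed
#' combinatorially from the design, independent of the detection pipeline:
#' the design table, all expected analog pairs and all expected cliffs with
#' category flags and extension statuses.
#'
#' @param spec a [fixture_spec()].
#' @return list with `activity` (tibble in the default ChEMBL column
#'   dialect), `design`, and `truth` (list of `pairs` and `cliffs` tibbles).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr_seed <- spec$seed
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(withr_seed)
  design <- fixture_design(spec)
  truth <- fixture_truth(design)
  rows <- design[rep(seq_len(nrow(design)), each = spec$n_replicates), ,
                 drop = FALSE]
  activity <- tibble::tibble(
    molecule_chembl_id = rows$compound_id,
    canonical_smiles = rows$smiles,
    target_chembl_id = rows$target_id,
    target_organism = "Homo sapiens",
    relationship_type = "D",
    confidence_score = 9L,
    standard_type = "Ki",
    standard_relation = "=",
    standard_value = 10^(9 - rows$pki),
    standard_units = "nM")
  list(activity = activity, design = design, truth = truth)
}

#' Inject rows that the pipeline must filter or standardize away
#'
#' Adds corrupted duplicates of the activity rows; a correct pipeline run on
#' the corrupted table gives the same result as on the clean table, so the
#' truth object is unchanged.
#'
#' @param activity activity tibble from [generate_fixture()].
#' @param modes subset of `"bad-units"` (unconvertible units),
#'   `"relation-gt"` (censored `">"` measurements), `"low-confidence"`
#'   (confidence score 8) and `"salt-forms"` (hydrochloride duplicates of
#'   existing compounds with the same value).
#' @return the activity tibble with corrupted rows appended.
#' @export
corrupt_fixture <- function(activity,
                            modes = c("bad-units", "relation-gt",
                                      "low-confidence", "salt-forms")) {
  modes <- match.arg(modes, several.ok = TRUE)
  out <- activity
  if ("bad-units" %in% modes) {
    r <- activity
    r$standard_units <- "ug.mL-1"
    r$standard_value <- r$standard_value * 7
    out <- dplyr::bind_rows(out, r)
  }
  if ("relation-gt" %in% modes) {
    r <- activity
    r$standard_relation <- ">"
    r$standard_value <- r$standard_value * 1000
    out <- dplyr::bind_rows(out, r)
  }
  if ("low-confidence" %in% modes) {
    r <- activity
    r$confidence_score <- 8L
    r$standard_value <- r$standard_value / 500
    out <- dplyr::bind_rows(out, r)
  }
  if ("salt-forms" %in% modes) {
    r <- activity
    r$canonical_smiles <- paste0(r$canonical_smiles, ".Cl")
    out <- dplyr::bind_rows(out, r)
  }
  out
}

#' Random small molecules for property-based testing
#'
#' Generates parseable SMILES of random acyclic trees and randomly decorated
#' ring systems, capped at `max_heavy` heavy atoms.
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @param max_heavy maximum heavy-atom count.
#' @return character vector of SMILES.
#' @export
random_molecules <- function(n, seed = 1L, max_heavy = 20L) {
  set.seed(seed)
  rings <- c("c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1", "C1CCCCC1",
             "c1ccco1", "c1ccc2[nH]ccc2c1", "C1CCNCC1", "c1ccsc1")
  ring_heavy <- c(6L, 6L, 10L, 6L, 5L, 9L, 6L, 5L)
  chain <- function(len) {
    if (len <= 0L) return("")
    first <- sample(c("C", "N", "O", "F", "Cl"), 1,
                    prob = c(0.5, 0.15, 0.15, 0.1, 0.1))
    if (len == 1L) return(first)
    if (first %in% c("F", "Cl")) {
      paste0(first, paste(sample(c("C", "C", "C", "N", "O"), len - 1L,
                                 replace = TRUE), collapse = ""))
    } else {
      paste(sample(c("C", "C", "C", "N", "O"), len, replace = TRUE),
            collapse = "")
    }
  }
  vapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.35) {            # acyclic tree
      len <- sample(2:max_heavy, 1)
      s <- chain(len)
      if (len > 4 && len <= max_heavy - 1L && stats::runif(1) < 0.5) {
        # branch off an interior carbon (other atoms may lack free valence)
        ch <- strsplit(s, "")[[1]]
        pos <- which(ch == "C" & c(ch[-1], "") != "l")
        pos <- pos[pos >= 2 & pos < length(ch)]
        if (length(pos) > 0) {
          cut <- pos[sample.int(length(pos), 1)]
          # a branch bonds through its first atom: no halogen start
          br <- paste(sample(c("C", "C", "C", "N", "O"),
                             sample.int(min(3L, max_heavy - len), 1),
                             replace = TRUE), collapse = "")
          s <- paste0(substr(s, 1, cut), "(", br, ")",
                      substr(s, cut + 1, nchar(s)))
        }
      }
      s
    } else {                                  # decorated ring
      k <- sample(seq_along(rings), 1)
      room <- max_heavy - ring_heavy[k]
      if (room <= 0L || stats::runif(1) < 0.15) return(rings[k])
      paste0(chain(sample(1:min(6, room), 1)), rings[k])
    }
  }, character(1))
}
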