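# Single-cut fragmentation: every exocyclic (acyclic) single bond between two
# heavy atoms is cut in turn, yielding a core and a substituent fragment. The
# core must have at least `core_ratio` times as many heavy atoms as the
# substituent, and the substituent at most `max_sub_atoms` heavy atoms. The
# cut point on the core is capped by hydrogen (R -> H); the substituent keeps
# a labeled (*) attachment point.

as_igraph <- function(graph) {
  igraph::graph_from_edgelist(graph$bonds[, c("a1", "a2"), drop = FALSE],
                              directed = FALSE)
}

#' Enumerate cuttable bonds of a molecule
#'
#' A bond is cuttable when it is a single bond between two heavy atoms and
#' does not belong to a ring, so that deleting it yields exactly two connected
#' fragments.
#'
#' @param smiles a single SMILES string.
#' @return tibble with columns `a1`, `a2` (atom indices in the parsed heavy-atom
#'   graph, `a1 < a2`), one row per cuttable bond. Molecules with no acyclic
#'   single bond (e.g. benzene) give zero rows.
#' @export
#' @examples
#' enumerate_cuts("CCc1ccccc1")  # ethylbenzene: two cuttable bonds
enumerate_cuts <- function(smiles) {
  g <- smiles_graph(smiles)
  if (is.null(g)) {
    stop("cannot parse SMILES: ", smiles, call. = FALSE)
  }
  empty <- tibble::tibble(a1 = integer(), a2 = integer())
  if (nrow(g$bonds) == 0L) return(empty)
  ig <- igraph::add_vertices(as_igraph(g),
                             max(0L, length(g$symbol) - max(g$bonds[, 1:2])))
  bridge_ids <- igraph::bridges(ig)
  if (length(bridge_ids) == 0L) return(empty)
  el <- igraph::as_edgelist(ig)[as.integer(bridge_ids), , drop = FALSE]
  # bond order lookup keyed on the unordered atom pair
  key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  ord <- g$bonds[, "order"][match(key(el[, 1], el[, 2]),
                                  key(g$bonds[, "a1"], g$bonds[, "a2"]))]
  el <- el[ord == 1L, , drop = FALSE]
  tibble::tibble(a1 = as.integer(pmin(el[, 1], el[, 2])),
                 a2 = as.integer(pmax(el[, 1], el[, 2])))
}

#' Core/substituent size rules
#'
#' A cut qualifies when the core has at least `core_ratio` times as many
#' heavy atoms as the substituent and the substituent has at most
#' `max_sub_atoms` heavy atoms.
#'
#' @param core_heavy,sub_heavy integer heavy-atom counts (vectorized).
#' @param max_sub_atoms maximum substituent size in heavy atoms.
#' @param core_ratio minimum core:substituent heavy-atom ratio.
#' @return logical vector.
#' @export
apply_size_rules <- function(core_heavy, sub_heavy, max_sub_atoms = 13,
                             core_ratio = 2) {
  stopifnot(all(core_heavy >= 1), all(sub_heavy >= 1))
  core_heavy >= core_ratio * sub_heavy & sub_heavy <= max_sub_atoms
}

# Position classes of a capped core: each heavy atom is labeled by the
# canonical SMILES of the core with a dummy (*) atom attached there; atoms
# with equal labels are topologically equivalent (same automorphism orbit).
# Integer classes are ranks of the sorted unique labels, so they depend only
# on the core's graph, never on input atom numbering.

#' Symmetry position classes of a core
#'
#' @param core_smiles canonical SMILES of an H-capped core.
#' @return tibble with one row per heavy atom: `atom`, `marker_smiles` (core
#'   with a `*` attachment at that atom, canonicalized) and integer `class`.
#' @export
#' @examples
#' core_position_classes("c1ccccc1")   # benzene: a single class
core_position_classes <- function(core_smiles) {
  key <- paste0("poscls|", core_smiles)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  g <- smiles_graph(core_smiles)
  if (is.null(g)) {
    stop("cannot parse core SMILES: ", core_smiles, call. = FALSE)
  }
  marker <- vapply(seq_along(g$symbol), function(i) {
    component_smiles(g, seq_along(g$symbol), marker_at = i)
  }, character(1))
  cls <- match(marker, sort(unique(marker)))
  cache_set(key, tibble::tibble(atom = seq_along(g$symbol),
                                marker_smiles = marker,
                                class = as.integer(cls)))
}

# Shared worker: evaluate one cut of a parsed molecule. Returns a one-row
# tibble or NULL when the size rules reject the cut.
evaluate_cut <- function(graph, ig, a1, a2, max_sub_atoms, core_ratio) {
  ig_cut <- igraph::delete_edges(ig, igraph::get_edge_ids(ig, c(a1, a2)))
  memb <- igraph::components(ig_cut)$membership
  side1 <- which(memb == memb[a1])
  side2 <- which(memb == memb[a2])
  if (length(side1) >= length(side2)) {
    core_atoms <- side1; sub_atoms <- side2
    core_cut <- a1; sub_cut <- a2
  } else {
    core_atoms <- side2; sub_atoms <- side1
    core_cut <- a2; sub_cut <- a1
  }
  if (!apply_size_rules(length(core_atoms), length(sub_atoms),
                        max_sub_atoms, core_ratio)) {
    return(NULL)
  }
  core_smiles <- component_smiles(graph, core_atoms)
  sub_smiles <- component_smiles(graph, sub_atoms, marker_at = sub_cut)
  marker <- component_smiles(graph, core_atoms, marker_at = core_cut)
  cls_table <- core_position_classes(core_smiles)
  cls <- cls_table$class[match(marker, cls_table$marker_smiles)]
  if (is.na(cls)) {
    stop("position-class lookup failed for core ", core_smiles, call. = FALSE)
  }
  tibble::tibble(core_smiles = core_smiles, sub_smiles = sub_smiles,
                 position_class = cls,
                 core_heavy = length(core_atoms),
                 sub_heavy = length(sub_atoms))
}

#' Cap and classify a single cut
#'
#' Cuts the given bond, takes the larger side as core (capped with hydrogen
#' at the cut point) and the smaller as substituent (with a `*` attachment
#' label), and assigns the symmetry position class of the attachment atom in
#' the capped core.
#'
#' @param smiles parent molecule SMILES.
#' @param a1,a2 atom indices of the bond to cut (as from [enumerate_cuts()]).
#' @inheritParams apply_size_rules
#' @return one-row tibble (`core_smiles`, `sub_smiles`, `position_class`,
#'   `core_heavy`, `sub_heavy`), or a zero-row tibble when the cut fails the
#'   size rules.
#' @export
cap_and_classify <- function(smiles, a1, a2, max_sub_atoms = 13,
                             core_ratio = 2) {
  g <- smiles_graph(smiles)
  if (is.null(g)) stop("cannot parse SMILES: ", smiles, call. = FALSE)
  ig <- igraph::add_vertices(
    if (nrow(g$bonds) > 0) as_igraph(g) else igraph::make_empty_graph(0, FALSE),
    max(0L, length(g$symbol) -
          if (nrow(g$bonds) > 0) max(g$bonds[, 1:2]) else 0L))
  row <- evaluate_cut(g, ig, a1, a2, max_sub_atoms, core_ratio)
  if (is.null(row)) {
    tibble::tibble(core_smiles = character(), sub_smiles = character(),
                   position_class = integer(), core_heavy = integer(),
                   sub_heavy = integer())
  } else {
    row
  }
}

#' Fragment a compound by all qualifying single cuts
#'
#' Applies [enumerate_cuts()], the size rules and H-capping to a molecule and
#' returns all distinct decompositions.
#'
#' @param smiles parent molecule SMILES (standardized).
#' @param compound_id identifier carried through to the output.
#' @inheritParams apply_size_rules
#' @return tibble with columns `compound_id`, `core_smiles`, `sub_smiles`,
#'   `position_class`, `core_heavy`, `sub_heavy`, deduplicated on
#'   (`core_smiles`, `sub_smiles`, `position_class`).
#' @export
#' @examples
#' fragment_compound("CCc1ccccc1")  # benzene+ethyl and toluene+methyl
fragment_compound <- function(smiles, compound_id = NA_character_,
                              max_sub_atoms = 13, core_ratio = 2) {
  cuts <- enumerate_cuts(smiles)
  empty <- tibble::tibble(compound_id = character(), core_smiles = character(),
                          sub_smiles = character(), position_class = integer(),
                          core_heavy = integer(), sub_heavy = integer())
  if (nrow(cuts) == 0L) return(empty)
  g <- smiles_graph(smiles)
  ig <- igraph::add_vertices(as_igraph(g),
                             max(0L, length(g$symbol) - max(g$bonds[, 1:2])))
  rows <- lapply(seq_len(nrow(cuts)), function(i) {
    evaluate_cut(g, ig, cuts$a1[i], cuts$a2[i], max_sub_atoms, core_ratio)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- dplyr::bind_rows(rows)
  out <- dplyr::distinct(out, .data$core_smiles, .data$sub_smiles,
                         .data$position_class, .keep_all = TRUE)
  dplyr::bind_cols(tibble::tibble(compound_id = rep(compound_id, nrow(out))),
                   out)
}

#' Fragment a table of compounds
#'
#' @param compounds tibble with columns `compound_id` and `canonical_smiles`
#'   (one row per unique structure; extra columns are ignored).
#' @inheritParams apply_size_rules
#' @return row-bound [fragment_compound()] results with a `canonical_smiles`
#'   column identifying the parent structure.
#' @export
fragment_compounds <- function(compounds, max_sub_atoms = 13, core_ratio = 2) {
  uniq <- dplyr::distinct(compounds, .data$compound_id, .data$canonical_smiles)
  rows <- lapply(seq_len(nrow(uniq)), function(i) {
    fr <- fragment_compound(uniq$canonical_smiles[i], uniq$compound_id[i],
                            max_sub_atoms = max_sub_atoms,
                            core_ratio = core_ratio)
    if (nrow(fr) > 0) fr$canonical_smiles <- uniq$canonical_smiles[i]
    fr
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(compound_id = character(),
                          core_smiles = character(),
                          sub_smiles = character(),
                          position_class = integer(),
                          core_heavy = integer(), sub_heavy = integer(),
                          canonical_smiles = character())
  }
  out
}
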