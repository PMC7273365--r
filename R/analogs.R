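# Analog sets and dual-site / isomer analog pairs. Compounds active against
# the same target and sharing an H-capped core form an analog set; qualifying
# pairs carry their substituents at two different symmetry position classes.

#' Build analog sets from fragmentations and activities
#'
#' Joins fragmentations to per-target activities and groups members by
#' (target, core). Groups with fewer than two distinct compounds are dropped
#' since they cannot form pairs.
#'
#' @param fragmentations tibble from [fragment_compounds()].
#' @param activities tibble from [aggregate_potency()].
#' @return member tibble with columns `target_id`, `core_smiles`,
#'   `compound_id`, `canonical_smiles`, `sub_smiles`, `position_class`,
#'   `sub_heavy`, `core_heavy`, `pki`; one analog set per unique
#'   (`target_id`, `core_smiles`).
#' @export
build_analog_sets <- function(fragmentations, activities) {
  members <- dplyr::inner_join(
    fragmentations,
    activities[, c("canonical_smiles", "target_id", "compound_id", "pki")],
    by = c("canonical_smiles", "compound_id"),
    relationship = "many-to-many")
  members <- dplyr::distinct(
    members, .data$target_id, .data$core_smiles, .data$compound_id,
    .data$sub_smiles, .data$position_class, .keep_all = TRUE)
  members <- dplyr::group_by(members, .data$target_id, .data$core_smiles)
  members <- dplyr::filter(members,
                           dplyr::n_distinct(.data$compound_id) >= 2L)
  members <- dplyr::ungroup(members)
  cols <- c("target_id", "core_smiles", "compound_id", "canonical_smiles",
            "sub_smiles", "position_class", "sub_heavy", "core_heavy", "pki")
  dplyr::arrange(members[, cols], .data$target_id, .data$core_smiles,
                 .data$compound_id, .data$position_class, .data$sub_smiles)
}

empty_pairs <- function() {
  tibble::tibble(target_id = character(), core_smiles = character(),
                 core_heavy = integer(),
                 cpd_a = character(), smiles_a = character(),
                 sub_a = character(), class_a = integer(),
                 sub_heavy_a = integer(), pki_a = numeric(),
                 cpd_b = character(), smiles_b = character(),
                 sub_b = character(), class_b = integer(),
                 sub_heavy_b = integer(), pki_b = numeric(),
                 pair_type = character(), size_diff = integer())
}

#' Enumerate analog pairs differing at two substitution sites
#'
#' Within each analog set, all unordered pairs of members with distinct
#' compounds, distinct position classes and a substituent heavy-atom size
#' difference of at most `max_size_diff` are enumerated. Pairs whose
#' substituents sit at the same position class (classic single-site analogs)
#' are excluded. A pair is of type `"iso"` when the two substituents are the
#' same fragment (the parents are then constitutional isomers), `"ds"`
#' otherwise. Member `a` is the one with the lexicographically smaller
#' compound id, so output is independent of input order.
#'
#' @param members analog-set member tibble from [build_analog_sets()].
#' @param max_size_diff maximum heavy-atom difference between the two
#'   substituents.
#' @return pair tibble; one row per (set, member-pair) combination. Use
#'   [dedupe_pairs()] to collapse to one row per compound pair.
#' @export
enumerate_pairs <- function(members, max_size_diff = 8) {
  if (nrow(members) == 0L) return(empty_pairs())
  a <- members
  names(a) <- c("target_id", "core_smiles", "cpd_a", "smiles_a", "sub_a",
                "class_a", "sub_heavy_a", "core_heavy", "pki_a")
  b <- members
  names(b) <- c("target_id", "core_smiles", "cpd_b", "smiles_b", "sub_b",
                "class_b", "sub_heavy_b", "core_heavy", "pki_b")
  pr <- dplyr::inner_join(a, b, by = c("target_id", "core_smiles",
                                       "core_heavy"),
                          relationship = "many-to-many")
  pr <- pr[pr$cpd_a < pr$cpd_b & pr$class_a != pr$class_b, , drop = FALSE]
  pr$size_diff <- abs(pr$sub_heavy_a - pr$sub_heavy_b)
  pr <- pr[pr$size_diff <= max_size_diff, , drop = FALSE]
  pr$pair_type <- ifelse(pr$sub_a == pr$sub_b, "iso", "ds")
  pr$size_diff <- as.integer(pr$size_diff)
  cols <- names(empty_pairs())
  tibble::as_tibble(pr[, cols])
}

#' Collapse analog pairs to one record per compound pair
#'
#' A compound pair may qualify through several alternative cores (or several
#' decompositions of one core). One record per unordered
#' (`target_id`, `cpd_a`, `cpd_b`) is kept: the one with the largest core
#' (ties: lexicographically smallest core SMILES, then `"iso"` before
#' `"ds"`, then lexicographic substituents). All supporting cores are listed
#' in an `evidence_cores` column and all observed pair types in
#' `evidence_types`.
#'
#' @param pairs pair tibble from [enumerate_pairs()].
#' @return deduplicated pair tibble with evidence columns.
#' @export
dedupe_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) {
    out <- empty_pairs()
    out$evidence_cores <- character()
    out$evidence_types <- character()
    return(out)
  }
  pr <- dplyr::group_by(pairs, .data$target_id, .data$cpd_a, .data$cpd_b)
  pr <- dplyr::mutate(
    pr,
    evidence_cores = paste(sort(unique(.data$core_smiles)), collapse = ";"),
    evidence_types = paste(sort(unique(.data$pair_type)), collapse = ";"))
  pr <- dplyr::arrange(pr, dplyr::desc(.data$core_heavy), .data$core_smiles,
                       .data$pair_type != "iso", .data$sub_a, .data$sub_b,
                       .data$class_a, .data$class_b, .by_group = TRUE)
  dplyr::ungroup(dplyr::slice_head(pr, n = 1L))
}
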