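# Reading compound-activity tables, high-confidence filtering, structure
# standardization and per-(structure, target) potency aggregation to pKi.

#' Default column mapping for ChEMBL-style activity exports
#'
#' Maps the internal record fields to the column headers of a ChEMBL activity
#' export. Override individual entries to read other dialects.
#'
#' @param ... named overrides, e.g. `smiles = "structure"`.
#' @return named character vector mapping internal field -> column name.
#' @export
chembl_mapping <- function(...) {
  m <- c(compound_id = "molecule_chembl_id",
         smiles = "canonical_smiles",
         target_id = "target_chembl_id",
         organism = "target_organism",
         assay_relationship_type = "relationship_type",
         assay_confidence_score = "confidence_score",
         measurement_type = "standard_type",
         relation = "standard_relation",
         value = "standard_value",
         units = "standard_units")
  over <- c(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(m))
    if (length(bad) > 0) {
      stop("unknown mapping field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    m[names(over)] <- over
  }
  m
}

empty_records <- function() {
  tibble::tibble(compound_id = character(), smiles = character(),
                 target_id = character(), organism = character(),
                 assay_relationship_type = character(),
                 assay_confidence_score = integer(),
                 measurement_type = character(), relation = character(),
                 value = numeric(), units = character())
}

#' Read an activity table
#'
#' Reads a TSV/CSV compound-activity table into activity records. Rows with an
#' unparseable numeric value or an empty SMILES are separated into a rejects
#' table with a `reason` column; unmapped extra columns are ignored.
#'
#' @param path file path.
#' @param mapping column mapping as from [chembl_mapping()].
#' @param sep field separator (default tab).
#' @param accepted_units optional character vector; when given, rows whose
#'   units are not in the set (case-insensitive) are rejected rather than
#'   failing later during aggregation.
#' @return list with `records` (tibble, one activity record per kept row) and
#'   `rejects` (the original columns of rejected rows plus `reason`).
#' @export
read_activity_table <- function(path, mapping = chembl_mapping(), sep = "\t",
                                accepted_units = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.delim(path, sep = sep, header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character"),
    error = function(e) NULL)   # a zero-byte file is an empty table
  if (is.null(raw) || nrow(raw) == 0L) {
    return(list(records = empty_records(),
                rejects = tibble::tibble(reason = character())))
  }
  missing_cols <- setdiff(unname(mapping), colnames(raw))
  if (length(missing_cols) > 0) {
    stop("mapped column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec <- tibble::as_tibble(stats::setNames(raw[, unname(mapping)],
                                           names(mapping)))
  rec$value <- suppressWarnings(as.numeric(rec$value))
  rec$assay_confidence_score <-
    suppressWarnings(as.integer(rec$assay_confidence_score))
  reason <- rep(NA_character_, nrow(rec))
  reason[is.na(rec$value)] <- "unparseable value"
  reason[is.na(rec$smiles) | !nzchar(trimws(rec$smiles))] <- "empty SMILES"
  if (!is.null(accepted_units)) {
    bad_units <- !(tolower(rec$units) %in% tolower(accepted_units))
    reason[is.na(reason) & bad_units] <-
      paste0("unknown units: ", rec$units[is.na(reason) & bad_units])
  }
  keep <- is.na(reason)
  rejects <- tibble::as_tibble(raw[!keep, , drop = FALSE])
  rejects$reason <- reason[!keep]
  list(records = rec[keep, , drop = FALSE], rejects = rejects)
}

#' High-confidence activity filter
#'
#' Keeps exactly the records that represent direct-interaction, top-confidence
#' equilibrium-constant measurements: organism equal to `organism` (default
#' human), assay relationship type `"D"`, assay confidence score 9,
#' measurement type `"Ki"` and relation `"="`. Row order is preserved and the
#' filter is idempotent.
#'
#' @param records activity-record tibble as from [read_activity_table()].
#' @param organism required organism value.
#' @param relationship_type required assay relationship type.
#' @param confidence_score required assay confidence score.
#' @param measurement_type required measurement type.
#' @param relation required relation.
#' @return the filtered tibble.
#' @export
filter_high_confidence <- function(records, organism = "Homo sapiens",
                                   relationship_type = "D",
                                   confidence_score = 9L,
                                   measurement_type = "Ki",
                                   relation = "=") {
  records[!is.na(records$organism) & records$organism == organism &
            records$assay_relationship_type == relationship_type &
            !is.na(records$assay_confidence_score) &
            records$assay_confidence_score == confidence_score &
            records$measurement_type == measurement_type &
            records$relation == relation, , drop = FALSE]
}

#' Standardize a structure
#'
#' Keeps the largest connected component (stripping salts/solvents),
#' neutralizes charges where chemically valid and returns the canonical
#' SMILES. Deterministic and idempotent: re-standardizing the output returns
#' the same string.
#'
#' @param smiles a single SMILES string.
#' @return canonical standardized SMILES.
#' @export
#' @examples
#' standardize_structure("CCO.Cl")   # ethanol, HCl stripped
standardize_structure <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  key <- paste0("std|", smiles)
  hit <- cache_get(key)
  if (!is.null(hit)) {
    if (is.na(hit)) stop("cannot parse SMILES: ", smiles, call. = FALSE)
    return(hit)
  }
  out <- ob_convert(smiles, "SMI", "CAN",
                    options = data.frame(names = c("r", "neutralize"),
                                         args = c("", "")))
  cache_set(key, out)
  if (is.na(out)) stop("cannot parse SMILES: ", smiles, call. = FALSE)
  out
}

standardize_structures <- function(smiles) {
  vapply(smiles, function(s) {
    tryCatch(standardize_structure(s), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
}

.unit_to_molar <- c(m = 1, mm = 1e-3, um = 1e-6, "µm" = 1e-6, nm = 1e-9,
                    pm = 1e-12)

#' Aggregate potency measurements to one pKi per compound and target
#'
#' Converts each Ki measurement to molar, takes pKi = -log10(Ki\[M\]) and
#' aggregates per (standardized structure, target) by the arithmetic mean.
#' Structures whose contributing pKi values span more than `pki_spread_max`
#' log units are discarded as irreproducible; duplicate structures under
#' different compound ids are merged (the lexicographically smallest id is
#' kept).
#'
#' @param records filtered activity records (see [filter_high_confidence()]).
#' @param pki_spread_max maximum allowed max-min spread of contributing pKi
#'   values, in log units.
#' @return tibble of compound activities: `compound_id`, `canonical_smiles`,
#'   `target_id`, `pki`, `n_measurements`, `pki_range`.
#' @export
aggregate_potency <- function(records, pki_spread_max = 1.0) {
  if (nrow(records) == 0L) {
    return(tibble::tibble(compound_id = character(),
                          canonical_smiles = character(),
                          target_id = character(), pki = numeric(),
                          n_measurements = integer(), pki_range = numeric()))
  }
  fac <- .unit_to_molar[tolower(records$units)]
  if (anyNA(fac)) {
    bad <- unique(records$units[is.na(fac)])
    stop("unknown unit(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(records$value <= 0)) {
    stop("non-positive Ki value in records", call. = FALSE)
  }
  rec <- records
  rec$pki <- -log10(rec$value * unname(fac))
  rec$canonical_smiles <- standardize_structures(rec$smiles)
  rec <- rec[!is.na(rec$canonical_smiles), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(rec, .data$canonical_smiles, .data$target_id),
    compound_id = min(.data$compound_id),
    n_measurements = dplyr::n(),
    pki_range = max(.data$pki) - min(.data$pki),
    pki = mean(.data$pki),
    .groups = "drop")
  out <- out[out$pki_range <= pki_spread_max, , drop = FALSE]
  out <- dplyr::arrange(out, .data$target_id, .data$compound_id)
  out[, c("compound_id", "canonical_smiles", "target_id", "pki",
          "n_measurements", "pki_range")]
}
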