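# End-to-end orchestration: ingest -> fragment -> analog pairs -> cliffs ->
# privileged-substructure annotation -> isomer extension, plus the
# deposition-style cliff table writer.

#' Pipeline configuration
#'
#' Collects the thresholds of the unified cliff search. Defaults are the
#' criteria of the underlying search protocol: 100-fold potency difference,
#' substituents of at most 13 heavy atoms, a core at least twice the
#' substituent size, at most 8 heavy atoms size difference between exchanged
#' substituents, a privileged-substructure frequency threshold of 100 unique
#' compounds, and at most 1 log unit spread between replicate pKi values.
#'
#' @param input path to the activity table (TSV/CSV), or `NULL` when an
#'   in-memory table is passed to [run_pipeline()].
#' @param ps_library path to a privileged-substructure pattern file, or
#'   `NULL` to skip PS annotation.
#' @param mapping column mapping, see [chembl_mapping()].
#' @param sep field separator of the input table.
#' @param organism organism kept by the high-confidence filter.
#' @param min_fold minimum potency fold difference for a cliff.
#' @param max_sub_atoms maximum substituent heavy atoms.
#' @param core_ratio minimum core:substituent heavy-atom ratio.
#' @param max_size_diff maximum substituent heavy-atom size difference.
#' @param ps_min_count frequency threshold for [screen_ps_frequency()].
#' @param ps_screen logical; screen the PS library against this dataset's
#'   compounds before annotation. Off by default: the frequency screen is
#'   meant to run against a large reference compound collection, not the
#'   (usually much smaller) cliff dataset itself.
#' @param ps_scope where PS patterns are matched (see
#'   [annotate_privileged()]).
#' @param pki_spread_max maximum replicate pKi spread.
#' @param accepted_units unit whitelist for ingest.
#' @param out_dir optional output directory for [run_pipeline()] dumps.
#' @param seed integer seed recorded in the config (the search itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, ps_library = NULL,
                       mapping = chembl_mapping(), sep = "\t",
                       organism = "Homo sapiens", min_fold = 100,
                       max_sub_atoms = 13, core_ratio = 2, max_size_diff = 8,
                       ps_min_count = 100, ps_screen = FALSE,
                       ps_scope = "core", pki_spread_max = 1.0,
                       accepted_units = c("nM", "uM", "µM", "M"),
                       out_dir = NULL, seed = 1L) {
  stopifnot(min_fold > 0, max_sub_atoms > 0, core_ratio > 0,
            max_size_diff > 0, ps_min_count > 0, pki_spread_max > 0)
  structure(list(input = input, ps_library = ps_library, mapping = mapping,
                 sep = sep, organism = organism, min_fold = min_fold,
                 max_sub_atoms = max_sub_atoms, core_ratio = core_ratio,
                 max_size_diff = max_size_diff, ps_min_count = ps_min_count,
                 ps_screen = ps_screen, ps_scope = ps_scope,
                 pki_spread_max = pki_spread_max,
                 accepted_units = accepted_units, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Map an in-memory raw table (input dialect) to activity records, applying
# the same reject rules as read_activity_table().
records_from_table <- function(raw, mapping = chembl_mapping(),
                               accepted_units = NULL) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(raw, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  read_activity_table(tmp, mapping = mapping, accepted_units = accepted_units)
}

#' Run the unified activity-cliff search
#'
#' Executes the full pipeline and returns the categorized cliff table with
#' stage-by-stage counts.
#'
#' @param config a [run_config()].
#' @param activity optional in-memory activity table (same columns as the
#'   input dialect); overrides `config$input`.
#' @return list with `cliffs` (extended cliff tibble), `activities`,
#'   `fragmentations`, `members`, `pairs` (deduplicated analog pairs),
#'   `rejects` and `summary` (named integer vector of stage counts).
#' @export
run_pipeline <- function(config = run_config(), activity = NULL) {
  stopifnot(inherits(config, "run_config"))
  loaded <- if (!is.null(activity)) {
    records_from_table(activity, config$mapping, config$accepted_units)
  } else {
    if (is.null(config$input)) {
      stop("run_pipeline needs config$input or an in-memory table",
           call. = FALSE)
    }
    read_activity_table(config$input, config$mapping, sep = config$sep,
                        accepted_units = config$accepted_units)
  }
  records <- filter_high_confidence(loaded$records, organism = config$organism)
  activities <- aggregate_potency(records,
                                  pki_spread_max = config$pki_spread_max)
  frags <- fragment_compounds(activities,
                              max_sub_atoms = config$max_sub_atoms,
                              core_ratio = config$core_ratio)
  members <- build_analog_sets(frags, activities)
  pairs <- dedupe_pairs(enumerate_pairs(members,
                                        max_size_diff = config$max_size_diff))
  cliffs <- call_cliffs(pairs, min_fold = config$min_fold)
  ps <- NULL
  if (!is.null(config$ps_library)) {
    ps <- read_ps_library(config$ps_library)
    if (isTRUE(config$ps_screen)) {
      ps <- screen_ps_frequency(ps, activities,
                                min_count = config$ps_min_count)
    }
    cliffs <- annotate_privileged(cliffs, ps, scope = config$ps_scope)
  }
  cliffs <- extend_cliffs(cliffs, members)
  summary <- c(
    n_records_read = nrow(loaded$records),
    n_records_rejected = nrow(loaded$rejects),
    n_records_high_confidence = nrow(records),
    n_compounds = length(unique(activities$canonical_smiles)),
    n_targets = length(unique(activities$target_id)),
    n_analog_sets = nrow(dplyr::distinct(members, .data$target_id,
                                         .data$core_smiles)),
    n_analog_pairs = nrow(pairs),
    n_acs = nrow(cliffs),
    n_ds_acs = sum(cliffs$is_ds),
    n_iso_acs = sum(cliffs$is_iso),
    n_ps_acs = sum(cliffs$is_ps),
    n_nonps_acs = sum(!cliffs$is_ps),
    n_ext_full = sum(cliffs$extension_status == "full"),
    n_ext_partial = sum(cliffs$extension_status == "partial"),
    n_ext_none = sum(cliffs$extension_status == "none"))
  res <- list(cliffs = cliffs, activities = activities,
              fragmentations = frags, members = members, pairs = pairs,
              rejects = loaded$rejects, ps_library = ps, summary = summary)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cliff_table(cliffs,
                      file.path(config$out_dir, "activity_cliffs.tsv"))
    if (nrow(loaded$rejects) > 0) {
      utils::write.table(loaded$rejects,
                         file.path(config$out_dir, "rejects.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(paste(names(summary), summary, sep = "\t"),
               file.path(config$out_dir, "summary.tsv"))
  }
  res
}

cliff_table_columns <- c(
  "ac_id", "target_id", "categories", "cpd1_id", "cpd1_smiles", "cpd1_pki",
  "cpd2_id", "cpd2_smiles", "cpd2_pki", "delta_pki", "core_smiles",
  "sub1_smiles", "pos1_class", "sub2_smiles", "pos2_class", "ps_smiles",
  "extension_status", "iso_of_potent_id", "iso_of_weak_id")

#' Format extended cliffs as the deposition table
#'
#' One row per cliff. Compound 1 is the highly potent partner, compound 2 the
#' weakly potent one; `categories` joins the membership flags from
#' \{`ds`, `iso`, `ps`\} with `";"` (every cliff is at least `ds`). pKi values
#' are printed with two decimals; empty fields are `""`. Rows are ordered by
#' `target_id`, then compound ids, and `ac_id` numbers that order, so
#' repeated runs are byte-identical.
#'
#' @param cliffs extended cliff tibble from [extend_cliffs()].
#' @return character-formatted tibble with the deposition columns.
#' @export
format_cliff_table <- function(cliffs) {
  n <- nrow(cliffs)
  if (n == 0L) {
    return(tibble::as_tibble(stats::setNames(
      as.list(rep(list(character()), length(cliff_table_columns))),
      cliff_table_columns)))
  }
  a_potent <- cliffs$potent_cpd == cliffs$cpd_a
  pick <- function(xa, xb, potent_first) ifelse(potent_first, xa, xb)
  out <- tibble::tibble(
    target_id = cliffs$target_id,
    categories = paste0("ds",
                        ifelse(cliffs$is_iso, ";iso", ""),
                        ifelse(cliffs$is_ps, ";ps", "")),
    cpd1_id = pick(cliffs$cpd_a, cliffs$cpd_b, a_potent),
    cpd1_smiles = pick(cliffs$smiles_a, cliffs$smiles_b, a_potent),
    cpd1_pki = sprintf("%.2f", pick(cliffs$pki_a, cliffs$pki_b, a_potent)),
    cpd2_id = pick(cliffs$cpd_b, cliffs$cpd_a, a_potent),
    cpd2_smiles = pick(cliffs$smiles_b, cliffs$smiles_a, a_potent),
    cpd2_pki = sprintf("%.2f", pick(cliffs$pki_b, cliffs$pki_a, a_potent)),
    delta_pki = sprintf("%.2f", cliffs$delta_pki),
    core_smiles = cliffs$core_smiles,
    sub1_smiles = pick(cliffs$sub_a, cliffs$sub_b, a_potent),
    pos1_class = as.character(pick(cliffs$class_a, cliffs$class_b, a_potent)),
    sub2_smiles = pick(cliffs$sub_b, cliffs$sub_a, a_potent),
    pos2_class = as.character(pick(cliffs$class_b, cliffs$class_a, a_potent)),
    ps_smiles = cliffs$ps_smarts,
    extension_status = cliffs$extension_status,
    iso_of_potent_id = cliffs$iso_of_potent_id,
    iso_of_weak_id = cliffs$iso_of_weak_id)
  out <- out[order(out$target_id, out$cpd1_id, out$cpd2_id), , drop = FALSE]
  dplyr::bind_cols(tibble::tibble(ac_id = sprintf("AC%05d", seq_len(n))),
                   out)
}

#' Write the cliff deposition table
#'
#' @param cliffs extended cliff tibble from [extend_cliffs()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_cliff_table <- function(cliffs, path) {
  tab <- format_cliff_table(cliffs)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a cliff deposition table back
#'
#' @param path TSV path written by [write_cliff_table()].
#' @return tibble with the deposition columns (all character).
#' @export
read_cliff_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE,
                                      colClasses = "character",
                                      check.names = FALSE))
}
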