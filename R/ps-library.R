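# Privileged-substructure library: loading pattern definitions and the
# frequency screen across unique bioactive structures. Privileged
# substructures are recurrent, family-directed core structures; here they are
# plain inputs (one SMARTS/SMILES pattern per line), never mined.

#' Read a privileged-substructure library
#'
#' Reads a pattern file with one record per line, `NAME<TAB>PATTERN`
#' (a bare pattern without a name is also accepted); `#` starts a comment.
#' Every pattern must compile as a substructure query; duplicates (identical
#' canonical patterns) are collapsed, keeping the first.
#'
#' @param path pattern file.
#' @return tibble with columns `name`, `pattern` and `n_compounds`
#'   (`NA` until [screen_ps_frequency()] is run).
#' @export
read_ps_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  name <- character(0)
  pattern <- character(0)
  for (i in keep) {
    parts <- strsplit(trimws(lines[i]), "\t", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      name <- c(name, parts[1]); pattern <- c(pattern, parts[1])
    } else {
      name <- c(name, parts[1]); pattern <- c(pattern, parts[2])
    }
    if (!valid_smarts(pattern[length(pattern)])) {
      stop("invalid substructure pattern at line ", i, ": ",
           pattern[length(pattern)], call. = FALSE)
    }
  }
  canon <- vapply(pattern, function(p) {
    cp <- ob_canonical(p)
    if (is.na(cp)) p else cp   # general SMARTS: dedupe on the raw string
  }, character(1), USE.NAMES = FALSE)
  first <- !duplicated(canon)
  tibble::tibble(name = name[first], pattern = pattern[first],
                 n_compounds = NA_integer_)
}

#' Screen privileged substructures by compound frequency
#'
#' Counts, for each pattern, the number of unique standardized structures
#' containing it at least once, and keeps the patterns found in at least
#' `min_count` structures. Uniqueness is by structure, not compound id, so a
#' structure registered under several ids counts once.
#'
#' @param ps_library tibble from [read_ps_library()].
#' @param compounds tibble with a `canonical_smiles` column (e.g. from
#'   [aggregate_potency()]), or a character vector of SMILES.
#' @param min_count minimum number of unique structures (default 100).
#' @return the library tibble with `n_compounds` filled, restricted to
#'   patterns meeting the threshold.
#' @export
screen_ps_frequency <- function(ps_library, compounds, min_count = 100) {
  smi <- if (is.character(compounds)) compounds else compounds$canonical_smiles
  smi <- unique(smi[!is.na(smi)])
  if (nrow(ps_library) == 0L) return(ps_library)
  counts <- if (length(smi) == 0L) {
    rep(0L, nrow(ps_library))
  } else {
    colSums(smarts_match_matrix(smi, ps_library$pattern))
  }
  ps_library$n_compounds <- as.integer(counts)
  ps_library[ps_library$n_compounds >= min_count, , drop = FALSE]
}
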