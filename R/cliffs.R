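# Activity-cliff calling, privileged-substructure annotation and the
# extended four-compound data structure for dual-site cliffs.

# Tolerance for pKi arithmetic at the cliff threshold: "at least 100-fold"
# is inclusive, so a computed delta of exactly 2.0 must qualify.
.pki_eps <- 1e-9

#' Call activity cliffs from analog pairs
#'
#' Keeps pairs whose potency difference is at least `min_fold`-fold, i.e.
#' `|pKi_a - pKi_b| >= log10(min_fold)` (inclusive). Every cliff is a
#' dual-site cliff (`is_ds`); isomer pairs additionally carry `is_iso`.
#' `is_ps` is initialized to `FALSE` and assigned by [annotate_privileged()].
#'
#' @param pairs deduplicated pair tibble from [dedupe_pairs()].
#' @param min_fold minimum potency fold difference (default 100).
#' @return cliff tibble: the pair columns plus `delta_pki`, `potent_cpd`,
#'   `weak_cpd`, `is_ds`, `is_iso`, `is_ps`, `ps_smarts`, `ps_evidence`.
#' @export
call_cliffs <- function(pairs, min_fold = 100) {
  if (nrow(pairs) > 0 && (anyNA(pairs$pki_a) || anyNA(pairs$pki_b))) {
    bad <- unique(c(pairs$cpd_a[is.na(pairs$pki_a)],
                    pairs$cpd_b[is.na(pairs$pki_b)]))
    stop("missing potency for compound(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cl <- pairs
  cl$delta_pki <- abs(cl$pki_a - cl$pki_b)
  cl <- cl[cl$delta_pki >= log10(min_fold) - .pki_eps, , drop = FALSE]
  cl$potent_cpd <- ifelse(cl$pki_a >= cl$pki_b, cl$cpd_a, cl$cpd_b)
  cl$weak_cpd <- ifelse(cl$pki_a >= cl$pki_b, cl$cpd_b, cl$cpd_a)
  cl$is_ds <- rep(TRUE, nrow(cl))
  cl$is_iso <- cl$pair_type == "iso"
  cl$is_ps <- rep(FALSE, nrow(cl))
  cl$ps_smarts <- rep("", nrow(cl))
  cl$ps_evidence <- rep("", nrow(cl))
  tibble::as_tibble(cl)
}

#' Annotate cliffs with privileged substructures
#'
#' Marks a cliff as a privileged-substructure cliff when a library pattern
#' occurs in it. With the default scope `"core"` the shared H-capped core is
#' matched, which guarantees the substructure is present in both cliff
#' partners; `"either"` and `"both"` match the two full molecules instead.
#' When several patterns match, `ps_smarts` reports the largest one by
#' heavy-atom count (ties: library order); all matches are listed in
#' `ps_evidence`.
#'
#' @param cliffs cliff tibble from [call_cliffs()].
#' @param ps_library tibble from [read_ps_library()] (columns `name`,
#'   `pattern`).
#' @param scope one of `"core"`, `"either"`, `"both"`.
#' @return the cliff tibble with `is_ps`, `ps_smarts`, `ps_evidence` filled.
#' @export
annotate_privileged <- function(cliffs, ps_library,
                                scope = c("core", "either", "both")) {
  scope <- match.arg(scope)
  if (nrow(cliffs) == 0L || nrow(ps_library) == 0L) return(cliffs)
  pat <- ps_library$pattern
  hits <- if (scope == "core") {
    subj <- unique(cliffs$core_smiles)
    smarts_match_matrix(subj, pat)[match(cliffs$core_smiles, subj), ,
                                   drop = FALSE]
  } else {
    subj <- unique(c(cliffs$smiles_a, cliffs$smiles_b))
    m <- smarts_match_matrix(subj, pat)
    ha <- m[match(cliffs$smiles_a, subj), , drop = FALSE]
    hb <- m[match(cliffs$smiles_b, subj), , drop = FALSE]
    if (scope == "either") ha | hb else ha & hb
  }
  sizes <- vapply(pat, pattern_heavy_atoms, numeric(1))
  pick <- apply(hits, 1L, function(h) {
    if (!any(h)) return(NA_integer_)
    which(h)[which.max(sizes[h])]
  })
  cliffs$is_ps <- !is.na(pick)
  cliffs$ps_smarts <- ifelse(cliffs$is_ps, pat[pick], "")
  cliffs$ps_evidence <- apply(hits, 1L, function(h) {
    paste(ps_library$name[h], collapse = ";")
  })
  cliffs
}

#' Extend dual-site cliffs with repositioned isomers
#'
#' For each cliff, searches the same analog set (same target and core) for
#' structural isomers of the cliff compounds with the substituent moved to
#' the other site: the potent compound's substituent at the weak compound's
#' position class (`iso_of_potent`) and vice versa (`iso_of_weak`). Found
#' isomers must be distinct structures from both cliff compounds and carry
#' their own pKi, so position-specific contributions to cliff formation can
#' be read off. `extension_status` is `"full"` when both slots are filled,
#' `"partial"` for exactly one, `"none"` otherwise.
#'
#' @param cliffs cliff tibble from [call_cliffs()] / [annotate_privileged()].
#' @param members analog-set member tibble from [build_analog_sets()].
#' @return the cliff tibble plus `iso_of_potent_id`, `iso_of_potent_pki`,
#'   `iso_of_weak_id`, `iso_of_weak_pki`, `extension_status`.
#' @export
extend_cliffs <- function(cliffs, members) {
  n <- nrow(cliffs)
  cliffs$iso_of_potent_id <- rep("", n)
  cliffs$iso_of_potent_pki <- rep(NA_real_, n)
  cliffs$iso_of_weak_id <- rep("", n)
  cliffs$iso_of_weak_pki <- rep(NA_real_, n)
  cliffs$extension_status <- rep("none", n)
  if (n == 0L) return(cliffs)
  find_iso <- function(i, sub, cls) {
    cand <- members[members$target_id == cliffs$target_id[i] &
                      members$core_smiles == cliffs$core_smiles[i] &
                      members$sub_smiles == sub &
                      members$position_class == cls &
                      !(members$canonical_smiles %in%
                          c(cliffs$smiles_a[i], cliffs$smiles_b[i])), ,
                    drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    cand[order(cand$compound_id), ][1L, ]
  }
  for (i in seq_len(n)) {
    a_potent <- cliffs$potent_cpd[i] == cliffs$cpd_a[i]
    sub_p <- if (a_potent) cliffs$sub_a[i] else cliffs$sub_b[i]
    cls_p <- if (a_potent) cliffs$class_a[i] else cliffs$class_b[i]
    sub_w <- if (a_potent) cliffs$sub_b[i] else cliffs$sub_a[i]
    cls_w <- if (a_potent) cliffs$class_b[i] else cliffs$class_a[i]
    ip <- find_iso(i, sub_p, cls_w)   # potent substituent at the weak site
    iw <- find_iso(i, sub_w, cls_p)   # weak substituent at the potent site
    if (!is.null(ip)) {
      cliffs$iso_of_potent_id[i] <- ip$compound_id
      cliffs$iso_of_potent_pki[i] <- ip$pki
    }
    if (!is.null(iw)) {
      cliffs$iso_of_weak_id[i] <- iw$compound_id
      cliffs$iso_of_weak_pki[i] <- iw$pki
    }
    k <- (!is.null(ip)) + (!is.null(iw))
    cliffs$extension_status[i] <- c("none", "partial", "full")[k + 1L]
  }
  cliffs
}
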