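# Low-level chemistry helpers on top of OpenBabel (via ChemmineOB/ChemmineR).
# Everything here works on heavy-atom graphs; hydrogens are implicit and are
# restored by the valence model whenever a fragment is written back out, which
# is what performs the R -> H capping after a cut.

.chem_cache <- new.env(parent = emptyenv())

cache_get <- function(key) {
  if (exists(key, envir = .chem_cache, inherits = FALSE)) {
    get(key, envir = .chem_cache, inherits = FALSE)
  } else {
    NULL
  }
}

cache_set <- function(key, value) {
  assign(key, value, envir = .chem_cache)
  value
}

ob_convert <- function(source, from = "SMI", to = "CAN", options = NULL) {
  opts <- if (is.null(options)) {
    data.frame(names = character(), args = character())
  } else {
    options
  }
  out <- tryCatch(
    ChemmineOB::convertFormat(from = from, to = to, source = source,
                              options = opts),
    error = function(e) ""
  )
  out <- sub("[ \t\r\n]+$", "", out)
  if (!nzchar(out)) NA_character_ else out
}

#' Canonical SMILES via OpenBabel
#'
#' Converts a SMILES string to OpenBabel's canonical form. The result is a
#' fixed point: re-canonicalizing it returns the same string.
#'
#' @param smiles a single SMILES string.
#' @return canonical SMILES, or `NA_character_` if the input does not parse.
#' @export
#' @examples
#' ob_canonical("C1=CC=CC=C1")
ob_canonical <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  key <- paste0("can|", smiles)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  cache_set(key, ob_convert(smiles, "SMI", "CAN"))
}

# molfile charge code <-> formal charge
.chg_from_code <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                    `5` = -1L, `6` = -2L, `7` = -3L)

#' Parse a SMILES string into a heavy-atom graph
#'
#' @param smiles a single SMILES string.
#' @return a list with `symbol` (element per atom), `charge` (formal charge
#'   per atom) and `bonds` (matrix with columns `a1`, `a2`, `order`, Kekule
#'   bond orders), or `NULL` if the structure does not parse.
#' @export
smiles_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  key <- paste0("graph|", smiles)
  hit <- cache_get(key)
  if (!is.null(hit)) return(if (is.logical(hit)) NULL else hit)
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) NULL)
  if (is.null(sdf)) {
    cache_set(key, NA)
    return(NULL)
  }
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  if (nrow(ab) == 0L) {
    cache_set(key, NA)
    return(NULL)
  }
  symbol <- sub("_.*$", "", rownames(ab))
  charge <- rep(0L, nrow(ab))
  if ("C6" %in% colnames(ab)) {
    code <- as.character(ab[, "C6"])
    charge <- unname(.chg_from_code[code])
    charge[is.na(charge)] <- 0L
  }
  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    matrix(integer(), ncol = 3L, dimnames = list(NULL, c("a1", "a2", "order")))
  } else {
    m <- unname(as.matrix(bb[, 1:3, drop = FALSE]))
    storage.mode(m) <- "integer"
    colnames(m) <- c("a1", "a2", "order")
    m
  }
  cache_set(key, list(symbol = symbol, charge = as.integer(charge),
                      bonds = bonds))
}

# Serialize a heavy-atom graph (optionally with a dummy * atom attached at
# `marker_at`) as a V2000 molfile. Coordinates are zero; implicit hydrogens
# are reconstructed from the valence model on reading.
graph_to_molfile <- function(symbol, charge, bonds, marker_at = NULL) {
  if (!is.null(marker_at)) {
    symbol <- c(symbol, "*")
    charge <- c(charge, 0L)
    bonds <- rbind(bonds, c(marker_at, length(symbol), 1L))
  }
  n <- length(symbol)
  nb <- nrow(bonds)
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, symbol)
  bond_lines <- if (nb > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1L], bonds[, 2L], bonds[, 3L])
  } else {
    character()
  }
  chg_lines <- character()
  chg_idx <- which(charge != 0L)
  if (length(chg_idx) > 0L) {
    grp <- split(chg_idx, ceiling(seq_along(chg_idx) / 8))
    chg_lines <- vapply(grp, function(ix) {
      paste0("M  CHG", sprintf("%3d", length(ix)),
             paste0(sprintf("%4d%4d", ix, charge[ix]), collapse = ""))
    }, character(1))
  }
  paste(c("", " sitecliffs", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
          atom_lines, bond_lines, chg_lines, "M  END", "$$$$"),
        collapse = "\n")
}

# Canonical SMILES of the induced subgraph on `keep`; `marker_at` (parent
# atom index, must be in `keep`) attaches a * dummy atom marking a position.
component_smiles <- function(graph, keep, marker_at = NULL) {
  keep <- sort(keep)
  idx <- match(seq_along(graph$symbol), keep)  # parent -> new index
  b <- graph$bonds
  sel <- b[, "a1"] %in% keep & b[, "a2"] %in% keep
  b <- b[sel, , drop = FALSE]
  b[, "a1"] <- idx[b[, "a1"]]
  b[, "a2"] <- idx[b[, "a2"]]
  mol <- graph_to_molfile(graph$symbol[keep], graph$charge[keep], b,
                          marker_at = if (is.null(marker_at)) NULL
                                      else idx[marker_at])
  ob_convert(mol, "MOL", "CAN")
}

#' Count heavy (non-hydrogen) atoms in a SMILES string
#'
#' @param smiles a single SMILES string.
#' @return integer heavy-atom count (`NA` if unparseable).
#' @export
heavy_atom_count <- function(smiles) {
  g <- smiles_graph(smiles)
  if (is.null(g)) NA_integer_ else length(g$symbol)
}

#' Molecular formula of a SMILES string
#'
#' Formula (including implicit hydrogens) as computed by OpenBabel, used e.g.
#' to confirm that isomer-cliff partners are constitutional isomers.
#'
#' @param smiles a single SMILES string.
#' @return formula string such as `"C8H10"`, or `NA_character_`.
#' @export
mol_formula <- function(smiles) {
  key <- paste0("mf|", smiles)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) NULL)
  out <- if (is.null(sdf)) {
    NA_character_
  } else {
    as.character(ChemmineR::propOB(sdf)$formula[1])
  }
  cache_set(key, out)
}

# Substructure match matrix: rows = smiles, cols = patterns (SMARTS or
# SMILES-as-SMARTS), entries TRUE where the pattern occurs in the molecule.
smarts_match_matrix <- function(smiles, patterns) {
  stopifnot(length(patterns) > 0L)
  m <- matrix(FALSE, nrow = length(smiles), ncol = length(patterns))
  # the OpenBabel SMARTS path needs at least one bond in the target molecule;
  # single-atom structures cannot contain any multi-atom pattern anyway
  ok <- !is.na(smiles) &
    vapply(smiles, function(s) isTRUE(heavy_atom_count(s) >= 2L), logical(1))
  if (!any(ok)) return(m)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles[ok]))
  for (j in seq_along(patterns)) {
    counts <- suppressWarnings(
      ChemmineR::smartsSearchOB(sdf, patterns[j], uniqueMatches = FALSE))
    m[ok, j] <- counts > 0
  }
  m
}

# TRUE if the pattern compiles as a SMARTS query.
valid_smarts <- function(pattern) {
  probe <- suppressWarnings(ChemmineR::smiles2sdf("CCO"))
  !inherits(tryCatch(
    suppressWarnings(ChemmineR::smartsSearchOB(probe, pattern,
                                               uniqueMatches = FALSE)),
    error = function(e) e), "error")
}

# Approximate heavy-atom count of a query pattern: exact when the pattern is
# plain SMILES, a token count for general SMARTS. Used only to rank matched
# privileged substructures by size.
pattern_heavy_atoms <- function(pattern) {
  n <- heavy_atom_count(pattern)
  if (!is.na(n)) return(n)
  body <- gsub("\\[[^]]*\\]", "Q", pattern)   # each bracket atom -> 1 token
  body <- gsub("[0-9()=#$:~@+.!,&;-]", "", body)
  toks <- gregexpr("Cl|Br|Q|[BCNOPSFIbcnops*]", body)[[1]]
  if (identical(toks[1], -1L)) 0L else length(toks)
}
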