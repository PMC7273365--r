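# Independent brute-force fragmentation oracle. Deliberately avoids the
# package's graph code: it deletes every bond in turn, checks connectivity
# with its own BFS, applies the size rules literally, serializes fragments
# through its own molfile writer, and decides whether two cuts are the same
# decomposition by exact colored-graph isomorphism (igraph VF2) between the
# cores with the cut atom marked. Aromatic bonds are identified by
# ChemmineR's ring perception so topologically equivalent Kekule forms
# compare equal.

oracle_parse <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  sym <- sub("_.*$", "", rownames(ab))
  codes <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
             `6` = -2L, `7` = -3L)
  chg <- if ("C6" %in% colnames(ab)) {
    unname(codes[as.character(ab[, "C6"])])
  } else {
    rep(0L, nrow(ab))
  }
  chg[is.na(chg)] <- 0L
  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    matrix(integer(), ncol = 3)
  } else {
    unname(as.matrix(bb[, 1:3, drop = FALSE]))
  }
  arom <- character()
  if (nrow(bonds) > 0L) {
    rg <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf[[1]], type = "all", arom = TRUE,
                                        inner = FALSE)),
      error = function(e) NULL)
    if (!is.null(rg) && length(rg$RINGS) > 0L) {
      for (ri in seq_along(rg$RINGS)) {
        if (!isTRUE(rg$AROMATIC[[ri]])) next
        at <- as.integer(sub("^.*_", "", rg$RINGS[[ri]]))
        pairs <- cbind(at, c(at[-1], at[1]))
        arom <- c(arom, paste(pmin(pairs[, 1], pairs[, 2]),
                              pmax(pairs[, 1], pairs[, 2])))
      }
    }
  }
  list(sym = sym, chg = chg, bonds = bonds, arom = unique(arom))
}

oracle_bfs <- function(n, edges, start) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n)
  queue <- start
  seen[start] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  which(seen)
}

oracle_molfile <- function(sym, chg, bonds) {
  hdr <- c("", " oracle", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   length(sym), nrow(bonds)))
  atoms <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0", sym)
  bl <- character(nrow(bonds))
  for (i in seq_len(nrow(bonds))) {
    bl[i] <- sprintf("%3d%3d%3d  0  0  0  0", bonds[i, 1], bonds[i, 2],
                     bonds[i, 3])
  }
  chgl <- character()
  for (i in which(chg != 0L)) {
    chgl <- c(chgl, sprintf("M  CHG  1%4d%4d", i, chg[i]))
  }
  paste(c(hdr, atoms, bl, chgl, "M  END", "$$$$"), collapse = "\n")
}

oracle_can <- function(sym, chg, bonds) {
  out <- ChemmineOB::convertFormat(
    "MOL", "CAN", oracle_molfile(sym, chg, bonds),
    options = data.frame(names = character(), args = character()))
  sub("[ \t\r\n]+$", "", out)
}

# Colored, edge-subdivided igraph of a fragment; `mark` (atom index) gets a
# unique extra color so isomorphism respects the cut position.
oracle_colored_graph <- function(sym, chg, bonds, arom, mark = NULL) {
  n <- length(sym)
  key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  bcol <- ifelse(key %in% arom, 99L, bonds[, 3])
  nb <- nrow(bonds)
  vlab <- paste(sym, chg)
  if (!is.null(mark)) vlab[mark] <- paste(vlab[mark], "CUT")
  if (nb == 0L) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    return(list(g = g, colors = as.integer(factor(vlab))))
  }
  edges <- matrix(0L, nrow = 2L * nb, ncol = 2L)
  for (i in seq_len(nb)) {
    edges[2 * i - 1L, ] <- c(bonds[i, 1], n + i)
    edges[2 * i, ] <- c(bonds[i, 2], n + i)
  }
  colors <- as.integer(factor(c(vlab, paste("B", bcol))))
  list(g = igraph::graph_from_edgelist(edges, directed = FALSE),
       colors = colors)
}

oracle_marked_iso <- function(f1, f2) {
  if (length(f1$sym) != length(f2$sym)) return(FALSE)
  g1 <- oracle_colored_graph(f1$sym, f1$chg, f1$bonds, f1$arom, f1$cut)
  g2 <- oracle_colored_graph(f2$sym, f2$chg, f2$bonds, f2$arom, f2$cut)
  # vf2 needs identical color alphabets; recode jointly
  lev <- sort(unique(c(g1$colors, g2$colors)))
  igraph::isomorphic(g1$g, g2$g, method = "vf2",
                     vertex.color1 = match(g1$colors, lev),
                     vertex.color2 = match(g2$colors, lev))
}

# All qualifying single-cut decompositions by brute force, one row per
# distinct (core, substituent, marked-core-isomorphism class).
oracle_fragment <- function(smiles, max_sub = 13, ratio = 2) {
  p <- oracle_parse(smiles)
  n <- length(p$sym)
  cuts <- list()
  if (nrow(p$bonds) > 0L) {
    for (k in seq_len(nrow(p$bonds))) {
      if (p$bonds[k, 3] != 1L) next
      rest <- p$bonds[-k, , drop = FALSE]
      a <- p$bonds[k, 1]; b <- p$bonds[k, 2]
      side_a <- oracle_bfs(n, rest, a)
      if (b %in% side_a) next                    # ring bond
      side_b <- oracle_bfs(n, rest, b)
      if (length(side_a) >= length(side_b)) {
        core_atoms <- side_a; sub_atoms <- side_b
        core_cut <- a; sub_cut <- b
      } else {
        core_atoms <- side_b; sub_atoms <- side_a
        core_cut <- b; sub_cut <- a
      }
      ch <- length(core_atoms); sh <- length(sub_atoms)
      if (!(ch >= ratio * sh && sh <= max_sub && sh >= 1)) next
      take <- function(atoms, cut_atom) {
        atoms <- sort(atoms)
        remap <- match(seq_len(n), atoms)
        bsel <- rest[rest[, 1] %in% atoms & rest[, 2] %in% atoms, ,
                     drop = FALSE]
        bsel[, 1] <- remap[bsel[, 1]]
        bsel[, 2] <- remap[bsel[, 2]]
        ar <- p$arom[vapply(strsplit(p$arom, " "), function(ij) {
          all(as.integer(ij) %in% atoms)
        }, logical(1))]
        ar <- vapply(strsplit(ar, " "), function(ij) {
          ij <- remap[as.integer(ij)]
          paste(min(ij), max(ij))
        }, character(1))
        list(sym = p$sym[atoms], chg = p$chg[atoms], bonds = bsel,
             arom = ar, cut = remap[cut_atom])
      }
      core <- take(core_atoms, core_cut)
      sub <- take(sub_atoms, sub_cut)
      cuts[[length(cuts) + 1L]] <- list(
        core = core,
        core_can = oracle_can(core$sym, core$chg, core$bonds),
        sub_can = oracle_can(c(sub$sym, "*"), c(sub$chg, 0L),
                             rbind(sub$bonds,
                                   c(sub$cut, length(sub$sym) + 1L, 1L))),
        core_heavy = ch, sub_heavy = sh)
    }
  }
  out <- data.frame(core = character(), sub = character(),
                    core_heavy = integer(), sub_heavy = integer())
  reps <- list()
  for (cu in cuts) {
    dup <- FALSE
    for (r in reps) {
      if (r$core_can == cu$core_can && r$sub_can == cu$sub_can &&
          oracle_marked_iso(r$core, cu$core)) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      reps[[length(reps) + 1L]] <- cu
      out <- rbind(out, data.frame(core = cu$core_can, sub = cu$sub_can,
                                   core_heavy = cu$core_heavy,
                                   sub_heavy = cu$sub_heavy))
    }
  }
  out
}
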