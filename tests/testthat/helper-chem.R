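# Chemistry helpers for tests: atom renumbering, molecule reconstruction and
# small table builders.

# Rewrite a SMILES with a random atom renumbering: permute the heavy-atom
# graph and write it back as a (non-canonical) SMILES in the new order.
permute_smiles <- function(smiles, seed = 1L) {
  g <- sitecliffs::smiles_graph(smiles)
  n <- length(g$symbol)
  if (n < 2L) return(smiles)
  set.seed(seed)
  perm <- sample.int(n)                    # perm[old] = new index
  b <- g$bonds
  b[, "a1"] <- perm[b[, "a1"]]
  b[, "a2"] <- perm[b[, "a2"]]
  inv <- order(perm)
  mol <- sitecliffs:::graph_to_molfile(g$symbol[inv], g$charge[inv], b)
  out <- sitecliffs:::ob_convert(mol, "MOL", "SMI")
  stopifnot(!is.na(out))
  out
}

# Reattach a substituent fragment (with * attachment label) at a
# representative atom of the given position class of a capped core; returns
# the canonical SMILES of the reassembled molecule.
reattach <- function(core_smiles, sub_smiles, position_class) {
  gc <- sitecliffs::smiles_graph(core_smiles)
  cls <- sitecliffs::core_position_classes(core_smiles)
  core_atom <- cls$atom[match(position_class, cls$class)]
  stopifnot(!is.na(core_atom))
  gs <- sitecliffs::smiles_graph(sub_smiles)
  star <- which(gs$symbol == "*")
  stopifnot(length(star) == 1L)
  att <- c(gs$bonds[gs$bonds[, "a1"] == star, "a2"],
           gs$bonds[gs$bonds[, "a2"] == star, "a1"])
  keep <- setdiff(seq_along(gs$symbol), star)
  remap <- match(seq_along(gs$symbol), keep)
  nb <- gs$bonds[gs$bonds[, "a1"] != star & gs$bonds[, "a2"] != star, ,
                 drop = FALSE]
  off <- length(gc$symbol)
  nb[, "a1"] <- remap[nb[, "a1"]] + off
  nb[, "a2"] <- remap[nb[, "a2"]] + off
  bonds <- rbind(gc$bonds, nb,
                 c(core_atom, remap[att] + off, 1L))
  mol <- sitecliffs:::graph_to_molfile(c(gc$symbol, gs$symbol[keep]),
                                       c(gc$charge, gs$charge[keep]), bonds)
  sitecliffs:::ob_convert(mol, "MOL", "CAN")
}

# Minimal well-formed activity table in the default ChEMBL dialect.
make_activity_table <- function(compound_id, smiles, value_nM,
                                target_id = "T001",
                                organism = "Homo sapiens",
                                relationship = "D", confidence = 9L,
                                type = "Ki", relation = "=",
                                units = "nM") {
  tibble::tibble(
    molecule_chembl_id = compound_id,
    canonical_smiles = smiles,
    target_chembl_id = target_id,
    target_organism = organism,
    relationship_type = relationship,
    confidence_score = confidence,
    standard_type = type,
    standard_relation = relation,
    standard_value = value_nM,
    standard_units = units)
}

write_activity_tsv <- function(tab, path = tempfile(fileext = ".tsv")) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

records_from <- function(tab) {
  sitecliffs:::records_from_table(tab)$records
}

starter_ps_path <- function() {
  system.file("extdata", "ps_library_starter.tsv", package = "sitecliffs")
}
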