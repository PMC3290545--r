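# Shared test helpers: small in-code fixtures, no stored data files.

# Build a domain_structure directly from C-alpha coordinates (bypasses file
# I/O for math-level tests).
toy_domain <- function(ca, resid = "ALA") {
  n <- nrow(ca)
  atoms <- data.frame(
    eleno = seq_len(n), elety = "CA", resid = resid, chain = "A",
    resno = seq_len(n), icode = "", x = ca[, 1], y = ca[, 2], z = ca[, 3],
    element = "C", het = FALSE, is_heavy = TRUE, entity = "1",
    stringsAsFactors = FALSE)
  structure(list(
    domain_id = "toy", atoms = atoms,
    residues = data.frame(chain = "A", resno = atoms$resno, icode = "",
                          resid = resid, entity = "1",
                          key = paste0("A|", atoms$resno, "|"),
                          stringsAsFactors = FALSE),
    cochains = atoms[0, ]), class = "domain_structure")
}

# A three-residue PDB text fixture with an altloc pair, a hydrogen and a
# hetero ligand in a second chain.
mini_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CA AGLY A   2       8.304   6.012  -4.443  1.00  0.00           C",
    "ATOM      4  CA BGLY A   2       9.304   6.012  -4.443  1.00  0.00           C",
    "ATOM      5  CA  SER A   3       7.010   7.880  -1.443  1.00  0.00           C",
    "ATOM      6  HA  SER A   3       7.110   7.980  -1.543  1.00  0.00           H",
    "TER",
    "HETATM    7  C1  SAS B 201       9.000   6.000  -3.000  1.00  0.00           C",
    "END")
}

write_mini_pdb <- function() {
  path <- tempfile(fileext = ".pdb")
  writeLines(mini_pdb_text(), path)
  path
}

# mmCIF fixture with two polymer entities and a hetero chain.
mini_cif_text <- function() {
  c("data_test",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 1.0 2.0 3.0 1.00 0.0 1 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 4.0 2.0 3.0 1.00 0.0 2 GLY A CA 1",
    "ATOM 3 C CA . ALA B 2 1 ? 8.0 2.0 3.0 1.00 0.0 1 ALA B CA 1",
    "HETATM 4 S S . SO4 C 3 . ? 9.0 2.0 3.0 1.00 0.0 101 SO4 B S 1")
}

write_mini_cif <- function() {
  path <- tempfile(fileext = ".cif")
  writeLines(mini_cif_text(), path)
  path
}

# Write a PDB with CA-only chains given as a named list of n x 3 matrices
# (protein chains) plus an optional ligand matrix (chain L, residue LIG).
write_chain_pdb <- function(chains, ligand = NULL, resid = "ALA") {
  path <- tempfile(fileext = ".pdb")
  lines <- character(0); serial <- 0L
  for (ch in names(chains)) {
    xyz <- chains[[ch]]
    rs <- if (is.character(resid)) rep_len(resid, nrow(xyz)) else resid[[ch]]
    for (i in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, rs[i], ch, i, xyz[i, 1], xyz[i, 2], xyz[i, 3]))
    }
    lines <- c(lines, "TER")
  }
  if (!is.null(ligand)) {
    for (i in seq_len(nrow(ligand))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d  C%d  LIG L%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, i, 900L, ligand[i, 1], ligand[i, 2], ligand[i, 3]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

residue_keys_of <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
}

resno_of_keys <- function(keys) {
  sort(as.integer(vapply(strsplit(keys, "|", fixed = TRUE), `[`,
                         character(1), 2)))
}

rotation_matrix <- function(axis = c(1, 1, 1), angle = 0.7) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  k <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * ca + sa * k + (1 - ca) * tcrossprod(a)
}
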