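# Fixtures are built in code at test time; nothing binary is stored.

# one PDB-format ATOM/HETATM line (fixed columns)
pdb_line <- function(record = "ATOM", serial, name, resname, chain, resno,
                     x, y, z, alt = " ", icode = " ", element = NULL) {
  if (is.null(element)) element <- substr(name, 1L, 1L)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, sprintf(" %-3s", name), alt, resname, chain, resno,
          icode, x, y, z, 1, 0, element)
}

write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# minimal structure: a lone ASN ND2 "probe" residue plus arbitrary charges
# at given positions (each its own LYS-NZ-style residue)
probe_structure <- function(charge_pos, charges) {
  stopifnot(nrow(charge_pos) == length(charges))
  atoms <- data.frame(
    name = c("ND2", rep("NZ", length(charges))),
    residue_name = c("ASN", rep("LYS", length(charges))),
    residue_number = seq_len(length(charges) + 1L),
    chain_id = "A",
    x = c(0, charge_pos[, 1]), y = c(0, charge_pos[, 2]),
    z = c(0, charge_pos[, 3]),
    partial_charge = c(0, charges),
    stringsAsFactors = FALSE)
  charged_structure(atoms, source_id = "probe", charge_model = "manual")
}

probe_locus <- function() {
  data.frame(chain_id = "A", residue_name = "ASN", residue_number = 1L,
             insertion_code = "", atom_name = "ND2",
             locus_class = "neutral_donor", label = "A:ASN 1:ND2",
             stringsAsFactors = FALSE)
}

# random point-charge structure, one single-atom residue per charge
rand_structure <- function(n, seed, box = 20) {
  set.seed(seed)
  atoms <- data.frame(
    name = "CA",
    residue_name = "GLY",
    residue_number = seq_len(n),
    chain_id = "A",
    x = runif(n, -box, box), y = runif(n, -box, box), z = runif(n, -box, box),
    partial_charge = runif(n, -1, 1),
    stringsAsFactors = FALSE)
  charged_structure(atoms, source_id = paste0("rand", seed),
                    charge_model = "manual")
}

# locus row pointing at atom i of structure s
locus_at <- function(s, i, locus_class = "neutral_donor") {
  a <- s$atoms[i, ]
  data.frame(chain_id = a$chain_id, residue_name = a$residue_name,
             residue_number = a$residue_number,
             insertion_code = a$insertion_code, atom_name = a$name,
             locus_class = locus_class,
             label = sprintf("%s:%s %s%s:%s", a$chain_id, a$residue_name,
                             a$residue_number, a$insertion_code, a$name),
             stringsAsFactors = FALSE)
}

# net-neutral toy partner: +q/-q dipole pair of single-atom residues
dipole_structure <- function(center, q = 0.5, sep = 0.8, id = "dipole") {
  atoms <- data.frame(
    name = "CA", residue_name = "GLY", residue_number = 1:2, chain_id = "A",
    x = center[1] + c(-sep / 2, sep / 2), y = center[2], z = center[3],
    partial_charge = c(q, -q), stringsAsFactors = FALSE)
  charged_structure(atoms, source_id = id, charge_model = "manual")
}

# toy binding partners in contact: a positively charged "protein" cluster
# facing a negatively charged "ligand" cluster, geometry jittered by seed
toy_complex <- function(seed, n_pos = 4, n_neg = 4, gap = 4) {
  set.seed(seed)
  prot <- data.frame(
    name = "NZ", residue_name = "LYS", residue_number = seq_len(n_pos),
    chain_id = "A",
    x = rnorm(n_pos, 0, 1.5), y = rnorm(n_pos, 0, 1.5),
    z = rnorm(n_pos, 0, 1.0),
    partial_charge = runif(n_pos, 0.5, 1),
    stringsAsFactors = FALSE)
  lig <- data.frame(
    name = "O1", residue_name = "SGN", residue_number = seq_len(n_neg),
    chain_id = "B",
    x = rnorm(n_neg, 0, 1.5), y = rnorm(n_neg, 0, 1.5),
    z = gap + rnorm(n_neg, 0, 1.0),
    partial_charge = runif(n_neg, -1, -0.5),
    stringsAsFactors = FALSE)
  list(protein = charged_structure(prot, "toy_prot", "manual"),
       ligand = charged_structure(lig, "toy_lig", "manual"))
}
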