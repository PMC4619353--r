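test_that("a hand-written PDB file reads back identically", {
  path <- write_pdb_lines(c(
    pdb_line("ATOM", 1, "N", "ALA", "A", 1, 1.234, -2.5, 3.75),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 2.001, -1.4, 3.5),
    pdb_line("ATOM", 3, "C", "ALA", "A", 1, 3.5, -1.9, 2.25)))
  s <- read_structure(path)
  expect_equal(n_atoms(s), 3L)
  expect_equal(s$atoms$name, c("N", "CA", "C"))
  expect_equal(coords(s),
               matrix(c(1.234, -2.5, 3.75, 2.001, -1.4, 3.5, 3.5, -1.9, 2.25),
                      ncol = 3, byrow = TRUE), ignore_attr = TRUE)
  expect_true(all(s$atoms$partial_charge == 0))
})

test_that("model selection and chain filtering obey PDB semantics", {
  atom <- pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0)
  atom2 <- pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 9, 9, 9)
  path <- write_pdb_lines(c("MODEL     1", atom, "ENDMDL",
                            "MODEL     2", atom2, "ENDMDL"))
  s1 <- read_structure(path, model_index = 1)
  s2 <- read_structure(path, model_index = 2)
  expect_equal(unname(coords(s1)[1, ]), c(0, 0, 0))
  expect_equal(unname(coords(s2)[1, ]), c(9, 9, 9))
  expect_error(read_structure(path, model_index = 3), "out of range")

  path2 <- write_pdb_lines(c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line("ATOM", 2, "CA", "GLY", "B", 1, 5, 0, 0)))
  sA <- read_structure(path2, chains = "A")
  expect_equal(sA$atoms$chain_id, "A")
  expect_error(read_structure(path2, chains = "Z"), "empty structure")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("cleaning removes waters, HETATMs, hydrogens and duplicate altlocs", {
  path <- write_pdb_lines(c(
    pdb_line("ATOM", 1, "N", "SER", "A", 1, 0, 0, 0),
    pdb_line("ATOM", 2, "CA", "SER", "A", 1, 1.5, 0, 0),
    pdb_line("ATOM", 3, "OG", "SER", "A", 1, 2.2, 1, 0, alt = "A"),
    pdb_line("ATOM", 4, "OG", "SER", "A", 1, 2.4, 1.2, 0, alt = "B"),
    pdb_line("ATOM", 5, "HG", "SER", "A", 1, 2.9, 1, 0, element = "H"),
    pdb_line("HETATM", 6, "O", "HOH", "A", 101, 8, 8, 8),
    pdb_line("HETATM", 7, "O", "HOH", "A", 102, 9, 9, 9),
    pdb_line("HETATM", 8, "S1", "SO4", "A", 201, -5, -5, -5, element = "S")))
  s <- read_structure(path)
  cl <- clean_structure(s)
  expect_equal(n_atoms(cl), 3L)           # N, CA, one OG
  expect_equal(sum(cl$atoms$name == "OG"), 1L)
  expect_equal(cl$atoms$x[cl$atoms$name == "OG"], 2.2)  # first conformer kept
  expect_true(all(cl$atoms$alt_loc == ""))
  keep_het <- clean_structure(s, keep_het = TRUE)
  expect_true("SO4" %in% keep_het$atoms$residue_name)
  expect_false("HOH" %in% keep_het$atoms$residue_name)
  # nothing removable: identity
  expect_equal(clean_structure(cl)$atoms, cl$atoms)
})

test_that("formal charge assignment matches its definition and is idempotent", {
  gly3 <- charged_structure(data.frame(
    name = rep(c("N", "CA", "C", "O"), 3),
    residue_name = "GLY",
    residue_number = rep(1:3, each = 4), chain_id = "A",
    x = seq_len(12), y = 0, z = 0, stringsAsFactors = FALSE))
  g <- assign_charges(gly3, "formal")
  expect_true(all(g$atoms$partial_charge == 0))

  lys <- charged_structure(data.frame(
    name = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
    residue_name = "LYS", residue_number = 1, chain_id = "A",
    x = seq_len(9), y = 0, z = 0, stringsAsFactors = FALSE))
  l <- assign_charges(lys, "formal")
  expect_equal(l$atoms$partial_charge[l$atoms$name == "NZ"], 1)
  expect_equal(sum(l$atoms$partial_charge[l$atoms$name != "NZ"]), 0)
  expect_identical(assign_charges(l, "formal")$atoms$partial_charge,
                   l$atoms$partial_charge)
})

test_that("packaged template models carry formal-charge-consistent sums", {
  for (nm in c("charmm-like", "mmff94-like")) {
    m <- charge_model(nm)
    arg <- m$templates[m$templates$residue_name == "ARG", ]
    side <- !(arg$atom_name %in% c("N", "CA", "C", "O"))
    expect_equal(sum(arg$charge[side]), 1, tolerance = 0.01)
    expect_silent(validate_charge_model(m))
  }
  # structure-level: single Arg under charmm-like sums to +1
  arg_atoms <- charge_model("charmm-like")$templates
  arg_atoms <- arg_atoms[arg_atoms$residue_name == "ARG", ]
  s <- charged_structure(data.frame(
    name = arg_atoms$atom_name, residue_name = "ARG", residue_number = 1,
    chain_id = "A", x = seq_len(nrow(arg_atoms)), y = 0, z = 0,
    stringsAsFactors = FALSE))
  expect_equal(net_charge(assign_charges(s, "charmm-like")), 1,
               tolerance = 0.01)
})

test_that("formal net charge counts Arg/Lys minus Asp/Glu exactly", {
  s <- make_structure(site_spec("specific", seed = 11))
  a <- s$atoms
  res <- a[!duplicated(paste(a$chain_id, a$residue_number)), "residue_name"]
  expected <- sum(res %in% c("ARG", "LYS")) - sum(res %in% c("ASP", "GLU"))
  expect_equal(net_charge(s), expected)
})

test_that("donor catalogs identify the documented loci", {
  mk <- function(resname, names) charged_structure(data.frame(
    name = names, residue_name = resname, residue_number = 1, chain_id = "A",
    x = seq_along(names), y = 0, z = 0, stringsAsFactors = FALSE))
  asn <- assign_charges(mk("ASN", c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2")), "formal")
  loci <- identify_loci(asn, "neutral_donor")
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$atom_name, "ND2")
  expect_equal(loci$label, "A:ASN 1:ND2")

  gly <- assign_charges(mk("GLY", c("N", "CA", "C", "O")), "formal")
  expect_equal(nrow(identify_loci(gly, "neutral_donor")), 0L)

  rk <- charged_structure(data.frame(
    name = c("NE", "NH1", "NH2", "CZ", "NZ"),
    residue_name = c(rep("ARG", 4), "LYS"),
    residue_number = c(rep(1, 4), 2), chain_id = "A",
    x = 1:5, y = 0, z = 0, stringsAsFactors = FALSE))
  basic <- identify_loci(assign_charges(rk, "formal"), "basic_donor")
  expect_equal(nrow(basic), 4L)
  expect_setequal(basic$atom_name, c("NE", "NH1", "NH2", "NZ"))

  # strict catalog drops Ser/Thr/Tyr/Trp donors
  ser <- assign_charges(mk("SER", c("N", "CA", "C", "O", "CB", "OG")), "formal")
  expect_equal(nrow(identify_loci(ser, "neutral_donor", catalog = "extended")), 1L)
  expect_equal(nrow(identify_loci(ser, "neutral_donor", catalog = "strict")), 0L)
})

test_that("locus output is sorted and invariant to atom order", {
  s <- make_structure(site_spec("specific", seed = 3))
  loci <- identify_loci(s, "neutral_donor")
  expect_false(is.unsorted(loci$residue_number))
  shuffled <- s
  set.seed(42)
  shuffled$atoms <- s$atoms[sample(nrow(s$atoms)), ]
  loci2 <- identify_loci(shuffled, "neutral_donor")
  expect_equal(loci2$label, loci$label)
})

test_that("in-silico mutation modes behave as documented", {
  asn <- charged_structure(data.frame(
    name = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
    residue_name = "ASN", residue_number = 5, chain_id = "A",
    x = 1:8, y = 0, z = 0, stringsAsFactors = FALSE))
  asn <- assign_charges(asn, "formal")
  ala <- mutate_residue(asn, "A", 5, "to_ala")
  expect_equal(unique(ala$atoms$residue_name), "ALA")
  expect_setequal(ala$atoms$name, c("N", "CA", "C", "O", "CB"))
  expect_equal(nrow(identify_loci(ala, "neutral_donor")), 0L)
  # to_ala on an Ala is the identity
  expect_equal(mutate_residue(ala, "A", 5, "to_ala")$atoms, ala$atoms)

  lys <- charged_structure(data.frame(
    name = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
    residue_name = "LYS", residue_number = 7, chain_id = "A",
    x = 1:9, y = 0, z = 0, stringsAsFactors = FALSE))
  lys <- assign_charges(lys, "formal")
  silenced <- mutate_residue(lys, "A", 7, "silence_charge")
  expect_equal(net_charge(silenced), net_charge(lys) - 1)

  swapped <- mutate_residue(asn, "A", 5, "charge_swap")
  side <- !(swapped$atoms$name %in% c("N", "CA", "C", "O", "OXT"))
  expect_equal(sum(swapped$atoms$partial_charge[side]), 1)
  expect_equal(sum(swapped$atoms$partial_charge[side] != 0), 1L)
  # swapped donor is no longer a neutral locus
  expect_equal(nrow(identify_loci(swapped, "neutral_donor")), 0L)

  expect_error(mutate_residue(asn, "A", 99, "to_ala"), "not found")
})

test_that("write/read round trip preserves atoms to PDB precision", {
  s <- make_structure(site_spec("specific", seed = 5))
  path <- tempfile(fileext = ".pdb")
  write_structure(s, path)
  s2 <- clean_structure(read_structure(path))
  expect_equal(n_atoms(s2), n_atoms(s))
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$residue_name, s$atoms$residue_name)
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3)
})

test_that("duplicate atoms and broken invariants are rejected", {
  dup <- data.frame(name = c("CA", "CA"), residue_name = "GLY",
                    residue_number = 1, chain_id = "A",
                    x = c(0, 1), y = 0, z = 0, stringsAsFactors = FALSE)
  expect_error(charged_structure(dup), "duplicate")
  bad <- data.frame(name = "CA", residue_name = "GLY", residue_number = 1,
                    chain_id = "A", x = NaN, y = 0, z = 0,
                    stringsAsFactors = FALSE)
  expect_error(charged_structure(bad), "coordinates")
})
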