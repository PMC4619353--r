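## Structure container and PDB I/O.
##
## A charged_structure is the object every calculation in the package
## consumes: an ordered atom table (PDB fields + coordinates in Angstrom)
## carrying one partial charge per atom, in elementary charge units.
## Crystal structures lack hydrogens, so the whole pipeline operates on
## heavy atoms with template charges; no protonation engine is provided.

#' Construct a charged structure from an atom table
#'
#' Low-level constructor; most users will obtain structures from
#' [read_structure()] or [make_structure()].
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `residue_name`, `residue_number`, `insertion_code`, `chain_id`,
#'   `alt_loc`, `record`, `x`, `y`, `z`, `partial_charge`. Missing
#'   `element`/`record`/`alt_loc`/`insertion_code`/`partial_charge`
#'   columns are filled with defaults.
#' @param source_id free-form identifier (e.g. a PDB code or file name).
#' @param charge_model name of the charge model applied, or `NA` if the
#'   structure is uncharged.
#'
#' @return An object of class `charged_structure`: a list with elements
#'   `atoms`, `source_id` and `charge_model`.
#' @export
charged_structure <- function(atoms, source_id = "unknown", charge_model = NA_character_) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$element)) atoms$element <- substr(trimws(atoms$name), 1L, 1L)
  if (is.null(atoms$insertion_code)) atoms$insertion_code <- ""
  if (is.null(atoms$alt_loc)) atoms$alt_loc <- ""
  if (is.null(atoms$record)) atoms$record <- "ATOM"
  if (is.null(atoms$partial_charge)) atoms$partial_charge <- 0
  required <- c("serial", "name", "element", "residue_name", "residue_number",
                "insertion_code", "chain_id", "alt_loc", "record",
                "x", "y", "z", "partial_charge")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0L)
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  atoms <- atoms[, required]
  atoms$residue_name <- toupper(atoms$residue_name)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (!all(is.finite(atoms$partial_charge)))
    stop("non-finite partial charges")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code,
               atoms$name, atoms$alt_loc)
  if (anyDuplicated(key))
    stop("duplicate atoms (same chain/residue/insertion/name/altloc)")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_id = source_id,
                 charge_model = charge_model),
            class = "charged_structure")
}

#' @export
print.charged_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("charged_structure '%s': %d atoms, %d residues, chains [%s]\n",
              x$source_id, nrow(a),
              length(unique(paste(a$chain_id, a$residue_number, a$insertion_code))),
              paste(unique(a$chain_id), collapse = ",")))
  cat(sprintf("  charge model: %s   net charge: %+.3f e\n",
              ifelse(is.na(x$charge_model), "<none>", x$charge_model),
              net_charge(x)))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `charged_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Net charge of a structure
#' @param s a `charged_structure`.
#' @return sum of atomic partial charges, in e.
#' @export
net_charge <- function(s) sum(s$atoms$partial_charge)

#' Atom coordinates as a matrix
#' @param s a `charged_structure`.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) into an uncharged
#' `charged_structure` (all partial charges zero). Multi-model files are
#' supported through `model_index`; atoms appear in file order.
#'
#' @param path path to a PDB file.
#' @param model_index 1-based MODEL block to read (default 1).
#' @param chains optional character vector of chain identifiers to keep.
#' @return A `charged_structure` with zero charges.
#' @export
read_structure <- function(path, model_index = 1L, chains = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     rm.insert = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e)))
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models)) n_models <- 1L
  if (model_index < 1L || model_index > n_models)
    stop("model_index ", model_index, " out of range (file has ",
         n_models, " model", if (n_models > 1L) "s", ")")
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
  blank <- function(v) ifelse(is.na(v), "", v)
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = blank(trimws(at$elesy)),
    residue_name = trimws(at$resid),
    residue_number = at$resno,
    insertion_code = blank(at$insert),
    chain_id = blank(at$chain),
    alt_loc = blank(at$alt),
    record = at$type,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    partial_charge = 0,
    stringsAsFactors = FALSE)
  if (!is.null(chains)) atoms <- atoms[atoms$chain_id %in% chains, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("empty structure: no atoms selected from '", path, "'")
  charged_structure(atoms, source_id = sub("\\.(pdb|ent)$", "", basename(path)))
}

#' Write a structure to a PDB file
#'
#' Emits standard ATOM/HETATM records. Coordinates are written with the
#' PDB's three decimals, so values survive a round trip to 1e-3 Angstrom.
#'
#' @param s a `charged_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  na_if_blank <- function(v) ifelse(v == "", NA, v)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords(s))),
                   type = a$record,
                   resno = a$residue_number,
                   resid = a$residue_name,
                   eleno = a$serial,
                   elety = a$name,
                   chain = na_if_blank(a$chain_id),
                   insert = na_if_blank(a$insertion_code),
                   alt = na_if_blank(a$alt_loc),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Remove waters, heteroatoms, hydrogens and alternate conformers
#'
#' Waters (HOH/WAT) are always dropped. HETATM records and hydrogens are
#' dropped unless requested. For alternate-location duplicates only the
#' first-listed conformer of each atom is retained (a deterministic
#' tie-break) and the alt_loc flag is cleared.
#'
#' @param s a `charged_structure`.
#' @param keep_het keep non-water HETATM records (default FALSE).
#' @param keep_hydrogens keep hydrogen atoms (default FALSE).
#' @return The cleaned `charged_structure` (possibly empty).
#' @export
clean_structure <- function(s, keep_het = FALSE, keep_hydrogens = FALSE) {
  a <- s$atoms
  keep <- !(a$residue_name %in% c("HOH", "WAT", "DOD"))
  if (!keep_het) keep <- keep & a$record != "HETATM"
  if (!keep_hydrogens) {
    is_h <- toupper(a$element) %in% c("H", "D") |
      (a$element == "" & grepl("^[0-9]*[HD]", a$name))
    keep <- keep & !is_h
  }
  a <- a[keep, , drop = FALSE]
  ## first-listed conformer wins for each (chain, residue, insertion, name)
  key <- paste(a$chain_id, a$residue_number, a$insertion_code, a$name)
  a <- a[!duplicated(key), , drop = FALSE]
  a$alt_loc <- ""
  out <- s
  out$atoms <- a
  rownames(out$atoms) <- NULL
  out
}

## residue index helper: integer id per (chain, resno, insert)
residue_key <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code, sep = "|")
}

#' Mutate a residue in silico
#'
#' Three perturbation modes used in hot-spot sensitivity analysis:
#' \describe{
#'   \item{`to_ala`}{sidechain atoms beyond CB removed, residue renamed
#'     ALA (classical alanine scan; charges of removed atoms vanish).}
#'   \item{`silence_charge`}{sidechain partial charges set to zero,
#'     geometry untouched.}
#'   \item{`charge_swap`}{sidechain charges zeroed and +1 e placed on the
#'     outermost retained sidechain atom, approximating an Arg/Lys
#'     substitution without building a rotamer (the electrostatic
#'     consequence depends on charge placement, not exact geometry).}
#' }
#'
#' @param s a `charged_structure`.
#' @param chain chain identifier of the target residue.
#' @param residue_number residue number of the target residue.
#' @param mode one of `"to_ala"`, `"silence_charge"`, `"charge_swap"`.
#' @param insertion_code insertion code of the target (default "").
#' @return The mutated `charged_structure`.
#' @export
mutate_residue <- function(s, chain, residue_number,
                           mode = c("to_ala", "silence_charge", "charge_swap"),
                           insertion_code = "") {
  mode <- match.arg(mode)
  a <- s$atoms
  hit <- a$chain_id == chain & a$residue_number == residue_number &
    a$insertion_code == insertion_code
  if (!any(hit))
    stop("residue ", chain, ":", residue_number, insertion_code, " not found")
  backbone <- c("N", "CA", "C", "O", "OXT")
  side <- hit & !(a$name %in% backbone)
  if (mode == "to_ala") {
    drop <- side & a$name != "CB"
    a <- a[!drop, , drop = FALSE]
    a$residue_name[a$chain_id == chain & a$residue_number == residue_number &
                     a$insertion_code == insertion_code] <- "ALA"
  } else if (mode == "silence_charge") {
    a$partial_charge[side] <- 0
  } else { # charge_swap
    a$partial_charge[side] <- 0
    if (any(side)) {
      ## outermost = largest remoteness letter in the PDB atom name
      ## (B < G < D < E < Z < H); first listed wins ties
      remoteness <- c(B = 1, G = 2, D = 3, E = 4, Z = 5, H = 6)
      lv <- remoteness[substr(a$name[side], 2L, 2L)]
      lv[is.na(lv)] <- 0
      target <- which(side)[which.max(lv)]
      a$partial_charge[target] <- 1
    }
  }
  out <- s
  out$atoms <- a
  rownames(out$atoms) <- NULL
  out
}
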