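## Donor-locus catalogs.
##
## A locus is one donor atom on the protein surface at which the
## multi-body potential is evaluated. Two classes:
##   basic_donor   - terminal sidechain nitrogens of Arg (NE, NH1, NH2)
##                   and Lys (NZ); the traditional view of a GAG site.
##   neutral_donor - uncharged hydrogen-bond donors. The strict catalog is
##                   Asn ND2 / Gln NE2; the extended catalog adds Ser OG,
##                   Thr OG1, Tyr OH, Trp NE1 and (when modelled neutral)
##                   His ND1/NE2.

BASIC_DONOR_CATALOG <- data.frame(
  residue_name = c("ARG", "ARG", "ARG", "LYS"),
  atom_name = c("NE", "NH1", "NH2", "NZ"),
  stringsAsFactors = FALSE)

NEUTRAL_DONOR_STRICT <- data.frame(
  residue_name = c("ASN", "GLN"),
  atom_name = c("ND2", "NE2"),
  stringsAsFactors = FALSE)

NEUTRAL_DONOR_EXTENDED <- rbind(
  NEUTRAL_DONOR_STRICT,
  data.frame(residue_name = c("SER", "THR", "TYR", "TRP", "HIS", "HIS"),
             atom_name = c("OG", "OG1", "OH", "NE1", "ND1", "NE2"),
             stringsAsFactors = FALSE))

#' Identify donor loci on a structure
#'
#' Lists the atoms of the requested donor class, ordered by chain then
#' residue number (so the result does not depend on atom order in the
#' input file). Neutral-donor loci are only reported while the residue's
#' sidechain is actually neutral under the assigned charge model
#' (|sidechain charge| < 0.25 e) - this excludes protonated histidine and
#' donors whose charge was swapped in silico.
#'
#' @param s a `charged_structure` with charges assigned.
#' @param locus_class `"neutral_donor"` or `"basic_donor"`.
#' @param catalog `"extended"` (default) or `"strict"` (Asn/Gln only) for
#'   neutral donors, or a custom data.frame with columns `residue_name`
#'   and `atom_name`.
#' @return A data.frame of class `locus_table` with one row per locus:
#'   `chain_id`, `residue_name`, `residue_number`, `insertion_code`,
#'   `atom_name`, `locus_class` and a `label` of the form
#'   `"CHAIN:RESNAME RESNUM:ATOM"`.
#' @export
identify_loci <- function(s, locus_class = c("neutral_donor", "basic_donor"),
                          catalog = "extended") {
  locus_class <- match.arg(locus_class)
  if (is.data.frame(catalog)) {
    cat_df <- catalog
    stopifnot(all(c("residue_name", "atom_name") %in% names(cat_df)))
  } else if (locus_class == "basic_donor") {
    cat_df <- BASIC_DONOR_CATALOG
  } else {
    cat_df <- switch(match.arg(catalog, c("extended", "strict")),
                     extended = NEUTRAL_DONOR_EXTENDED,
                     strict = NEUTRAL_DONOR_STRICT)
  }
  a <- s$atoms
  hit <- paste(a$residue_name, a$name) %in%
    paste(cat_df$residue_name, cat_df$atom_name)
  loci <- a[hit, c("chain_id", "residue_name", "residue_number",
                   "insertion_code", "name"), drop = FALSE]
  names(loci)[names(loci) == "name"] <- "atom_name"
  ## a donor only counts as neutral while its sidechain is uncharged
  ## under the assigned model (this drops protonated His, and donors
  ## whose charge was swapped in silico)
  if (locus_class == "neutral_donor" && nrow(loci) > 0L) {
    backbone <- c("N", "CA", "C", "O", "OXT")
    rk_all <- residue_key(a)
    side <- !(a$name %in% backbone)
    side_q <- tapply(a$partial_charge[side], rk_all[side], sum)
    rk_loci <- paste(loci$chain_id, loci$residue_number,
                     loci$insertion_code, sep = "|")
    q_res <- side_q[rk_loci]
    q_res[is.na(q_res)] <- 0
    loci <- loci[abs(q_res) < 0.25, , drop = FALSE]
  }
  ord <- order(loci$chain_id, loci$residue_number, loci$insertion_code,
               loci$atom_name)
  loci <- loci[ord, , drop = FALSE]
  loci$locus_class <- rep(locus_class, nrow(loci))
  loci$label <- locus_label(loci)
  rownames(loci) <- NULL
  class(loci) <- c("locus_table", "data.frame")
  loci
}

locus_label <- function(loci) {
  if (nrow(loci) == 0L) return(character(0))
  sprintf("%s:%s %s%s:%s", loci$chain_id, loci$residue_name,
          loci$residue_number, loci$insertion_code, loci$atom_name)
}

## row indices in s$atoms for each locus row; errors if a locus is stale
locus_atom_index <- function(s, loci) {
  a <- s$atoms
  idx <- match(paste(loci$chain_id, loci$residue_number, loci$insertion_code,
                     loci$atom_name),
               paste(a$chain_id, a$residue_number, a$insertion_code, a$name))
  if (anyNA(idx))
    stop("locus atom(s) not present in structure: ",
         paste(loci$label[is.na(idx)], collapse = ", "))
  idx
}
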