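## Multi-body Coulomb potential at donor loci.
##
## The potential "manifested at an atom by the rest of the structure" is
## the pairwise Coulomb sum
##
##   G_ES = probe_sign * sum_j 332.0636 * q_j / (eps(r_j) * r_j)
##
## over all atoms j outside the exclusion set, with r_j the distance (A)
## from the locus atom to atom j. The probe sign defaults to -1 so that
## an electropositive environment - the kind that attracts a polyanionic
## GAG - yields a negative ("high") G_ES; spots most conducive to binding
## negatively charged entities are then the most negative entries. No
## cutoff radius is applied: structures are desk-scale and the sum is
## exact.

#' Specify a dielectric model
#'
#' @param kind `"uniform"` (constant epsilon) or `"distance_dependent"`
#'   (epsilon(r) = epsilon * r, the common screened-Coulomb form).
#' @param epsilon positive dimensionless constant (uniform value, or slope
#'   of the distance-dependent form). Default 4, the middle of the usual
#'   protein-interior sweep 2/3/4/10.
#' @return An object of class `dielectric_model`.
#' @export
dielectric_model <- function(kind = c("uniform", "distance_dependent"),
                             epsilon = 4) {
  kind <- match.arg(kind)
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  structure(list(kind = kind, epsilon = epsilon), class = "dielectric_model")
}

#' @export
print.dielectric_model <- function(x, ...) {
  cat(sprintf("dielectric_model: %s, epsilon = %g\n", x$kind, x$epsilon))
  invisible(x)
}

## epsilon(r) * r, vectorized over distances
dielectric_denominator <- function(d, r) {
  switch(d$kind,
         uniform = d$epsilon * r,
         distance_dependent = d$epsilon * r * r)
}

#' Multi-body potential at one locus
#'
#' @param s a `charged_structure` with charges assigned.
#' @param locus a single row of a [identify_loci()] table (or a one-row
#'   data.frame with the same columns).
#' @param d a [dielectric_model()].
#' @param probe_sign -1 (default; negative = GAG-attractive) or +1 (raw
#'   electropositive potential).
#' @param exclusion `"residue"` (default: all atoms of the locus's own
#'   residue are excluded, avoiding self-polarization artifacts) or
#'   `"atom"` (only the locus atom itself).
#' @return G_ES in kcal/mol.
#' @export
locus_potential <- function(s, locus, d = dielectric_model(),
                            probe_sign = -1, exclusion = c("residue", "atom")) {
  exclusion <- match.arg(exclusion)
  stopifnot(nrow(locus) == 1L, probe_sign %in% c(-1, 1))
  a <- s$atoms
  i <- locus_atom_index(s, locus)
  excl <- if (exclusion == "residue") {
    residue_key(a) == residue_key(a[i, , drop = FALSE])
  } else {
    seq_len(nrow(a)) == i
  }
  dx <- a$x - a$x[i]; dy <- a$y - a$y[i]; dz <- a$z - a$z[i]
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  keep <- !excl
  if (any(keep & r < 1e-6))
    stop("coincident atom(s) at locus ", locus$label)
  if (!any(keep)) return(0)
  probe_sign * sum(COULOMB_KCAL * a$partial_charge[keep] /
                     dielectric_denominator(d, r[keep]))
}

#' Potential table over all loci of a class
#'
#' Evaluates [locus_potential()] at every locus returned by
#' [identify_loci()], in the same order. The table restricted to
#' neutral-donor loci is the structure's G_GAG-binding profile.
#'
#' @inheritParams locus_potential
#' @param locus_class `"neutral_donor"` or `"basic_donor"`.
#' @param catalog catalog selection passed to [identify_loci()].
#' @param loci optionally, a precomputed `locus_table` (overrides
#'   `locus_class`/`catalog`).
#' @return A data.frame of class `potential_table`: the locus columns plus
#'   `G_ES` (kcal/mol), with attributes `structure_id`, `dielectric`,
#'   `charge_model` and `probe_sign`.
#' @export
all_locus_potentials <- function(s, locus_class = "neutral_donor",
                                 d = dielectric_model(), probe_sign = -1,
                                 exclusion = "residue", catalog = "extended",
                                 loci = NULL) {
  if (is.null(loci)) loci <- identify_loci(s, locus_class, catalog = catalog)
  tab <- as.data.frame(loci)
  if (nrow(tab) == 0L) {
    tab$G_ES <- numeric(0)
  } else {
    a <- s$atoms
    idx <- locus_atom_index(s, tab)
    rk <- residue_key(a)
    xyz <- coords(s)
    q <- a$partial_charge
    tab$G_ES <- vapply(seq_len(nrow(tab)), function(k) {
      i <- idx[k]
      excl <- if (exclusion == "residue") rk == rk[i] else seq_along(q) == i
      dxyz <- sweep(xyz, 2L, xyz[i, ])
      r <- sqrt(rowSums(dxyz * dxyz))
      keep <- !excl
      if (any(keep & r < 1e-6))
        stop("coincident atom(s) at locus ", tab$label[k])
      if (!any(keep)) return(0)
      probe_sign * sum(COULOMB_KCAL * q[keep] /
                         dielectric_denominator(d, r[keep]))
    }, numeric(1))
  }
  structure(tab,
            structure_id = s$source_id,
            dielectric = d,
            charge_model = s$charge_model,
            probe_sign = probe_sign,
            class = c("potential_table", "data.frame"))
}

#' Aggregate a potential table to one entry per residue
#'
#' Whether binding footprints are best summarised per donor atom or per
#' residue is an open question; the default report is per atom, and this
#' helper collapses multi-donor residues (Arg, His) to their most negative
#' locus.
#'
#' @param t a `potential_table`.
#' @return A `potential_table` with one row per residue: the entry whose
#'   `G_ES` is the residue minimum.
#' @export
aggregate_per_residue <- function(t) {
  if (nrow(t) == 0L) return(t)
  key <- paste(t$chain_id, t$residue_number, t$insertion_code)
  keep <- unlist(lapply(split(seq_len(nrow(t)), key),
                        function(i) i[which.min(t$G_ES[i])]),
                 use.names = FALSE)
  out <- t[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a potential table as TSV
#'
#' Columns: structure_id, chain, residue_name, residue_number, atom_name,
#' locus_class, G_ES_kcal_mol.
#'
#' @param t a `potential_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_potential_table <- function(t, path) {
  out <- data.frame(structure_id = attr(t, "structure_id"),
                    chain = t$chain_id,
                    residue_name = t$residue_name,
                    residue_number = paste0(t$residue_number, t$insertion_code),
                    atom_name = t$atom_name,
                    locus_class = t$locus_class,
                    G_ES_kcal_mol = t$G_ES,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
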