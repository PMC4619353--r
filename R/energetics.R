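## Binding energetics: Kd conversion, decomposition, mutant-table
## regressions.
##
## Observed binding free-energy differences come from equilibrium
## constants, ddG_OBS = RT ln(Kd_variant / Kd_reference). Complex
## energetics are decomposed into an electrostatic interaction term
## (Coulomb cross-sum at the inner dielectric) and a desolvation term
## from a pluggable solver. The shipped desolvation solver is a
## Born-style surrogate: a contract-level continuum model (burial grows
## the effective Born radius; moving a charge from solvent dielectric 80
## toward interior dielectric 2 costs energy proportional to q^2). It
## honours the sign/opposition structure of a Poisson-Boltzmann
## decomposition without reproducing any particular solver's numbers.

#' Observed binding free-energy difference from Kd values
#'
#' ddG_OBS = R T ln(Kd_variant / Kd_reference), with
#' R = 1.9872e-3 kcal/(mol K).
#'
#' @param kd_variant dissociation constant of the variant (nM; any unit
#'   shared with the reference).
#' @param kd_reference dissociation constant of the reference variant.
#' @param temperature absolute temperature in K (default 298).
#' @return kcal/mol (vectorized).
#' @export
ddg_from_kd <- function(kd_variant, kd_reference, temperature = 298) {
  if (any(!is.finite(kd_variant)) || any(!is.finite(kd_reference)) ||
      any(kd_variant <= 0) || any(kd_reference <= 0))
    stop("Kd values must be positive and finite")
  if (temperature <= 0) stop("temperature must be positive")
  R_KCAL * temperature * log(kd_variant / kd_reference)
}

#' Coulomb interaction energy between two charged structures
#'
#' The full cross-sum over atom pairs (i in a, j in b) of
#' 332.0636 q_i q_j / (eps(r_ij) r_ij).
#'
#' @param a,b `charged_structure`s with charges assigned; they must not
#'   share atoms.
#' @param d a [dielectric_model()].
#' @return kcal/mol.
#' @export
coulomb_interaction_energy <- function(a, b, d = dielectric_model(epsilon = 2)) {
  xa <- coords(a); xb <- coords(b)
  qa <- a$atoms$partial_charge; qb <- b$atoms$partial_charge
  if (nrow(xa) == 0L || nrow(xb) == 0L) return(0)
  ## r_ij^2 via the expanded square; clamp tiny negatives from rounding
  r2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  r <- sqrt(pmax(r2, 0))
  if (any(r < 1e-6))
    stop("coincident atoms across partners")
  sum((qa %o% qb) * COULOMB_KCAL / dielectric_denominator(d, r))
}

## burial count: non-self heavy atoms within `radius` of each atom of s,
## optionally including a partner's atoms
burial_counts <- function(s, partner = NULL, radius = 6) {
  x <- coords(s)
  env <- if (is.null(partner)) x else rbind(x, coords(partner))
  n <- nrow(x)
  counts <- integer(n)
  r2max <- radius^2
  env_sq <- rowSums(env^2)
  for (i in seq_len(n)) {
    d2 <- env_sq - 2 * (env %*% x[i, ]) + sum(x[i, ]^2)
    counts[i] <- sum(d2 <= r2max) - 1L  # exclude self
  }
  counts
}

#' Born-style surrogate desolvation energy
#'
#' For each charged atom an effective Born radius grows linearly with its
#' burial (count of non-self heavy atoms within 6 A, including partner
#' atoms when in complex): R_born = 1.5 + 0.08 * burial (Angstrom). The
#' desolvation cost of complexation is
#'
#'   sum_i -166 q_i^2 (1/eps_out - 1/eps_in)
#'             (1/R_born,alone - 1/R_born,complex)
#'
#' with eps_in = 2, eps_out = 80. The term is guaranteed >= 0 whenever
#' burial only increases on complexation, and scales as q^2.
#'
#' @param s the `charged_structure` whose atoms are being desolvated.
#' @param partner the binding partner (its atoms add burial); `NULL`
#'   means no partner, giving exactly 0.
#' @param eps_in,eps_out interior and solvent dielectric constants.
#' @param radius burial-count radius in Angstrom.
#' @return desolvation energy of `s` upon complexation, kcal/mol.
#' @export
born_surrogate_desolvation <- function(s, partner = NULL, eps_in = 2,
                                       eps_out = 80, radius = 6) {
  if (is.null(partner)) return(0)
  q <- s$atoms$partial_charge
  b_alone <- burial_counts(s, NULL, radius)
  b_complex <- burial_counts(s, partner, radius)
  r_alone <- 1.5 + 0.08 * b_alone
  r_complex <- 1.5 + 0.08 * b_complex
  sum(-(COULOMB_KCAL / 2) * q^2 * (1 / eps_out - 1 / eps_in) *
        (1 / r_alone - 1 / r_complex))
}

#' Decompose a complex into electrostatic and desolvation components
#'
#' dG_ES is the Coulomb cross-term at the inner dielectric (default
#' uniform eps = 2); dG_DS is the complex-minus-parts desolvation from
#' the selected solver, i.e. the sum of each partner's
#' [born_surrogate_desolvation()] in the presence of the other.
#'
#' @param complex_protein,complex_ligand the two partners as
#'   `charged_structure`s, positioned as in the complex.
#' @param solver `"born_surrogate"` (default) or `"null"` (dG_DS = 0).
#' @param d dielectric model for the electrostatic term.
#' @param eps_in,eps_out dielectrics passed to the desolvation solver.
#' @return An object of class `energy_decomposition`: list with `dG_ES`,
#'   `dG_DS` (kcal/mol) and `solver`.
#' @export
decompose_interaction <- function(complex_protein, complex_ligand,
                                  solver = c("born_surrogate", "null"),
                                  d = dielectric_model(epsilon = 2),
                                  eps_in = 2, eps_out = 80) {
  solver <- match.arg(solver)
  dG_ES <- coulomb_interaction_energy(complex_protein, complex_ligand, d)
  dG_DS <- switch(solver,
                  null = 0,
                  born_surrogate =
                    born_surrogate_desolvation(complex_protein, complex_ligand,
                                               eps_in, eps_out) +
                    born_surrogate_desolvation(complex_ligand, complex_protein,
                                               eps_in, eps_out))
  structure(list(dG_ES = dG_ES, dG_DS = dG_DS, solver = solver),
            class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("dG_ES = %.3f kcal/mol   dG_DS = %.3f kcal/mol   (solver: %s)\n",
              x$dG_ES, x$dG_DS, x$solver))
  invisible(x)
}

#' Regression with a Shapiro-Wilk normality gate
#'
#' Ordinary least squares is always fitted (slope, intercept, OLS r^2).
#' When both series pass Shapiro-Wilk at alpha, the reported correlation
#' statistic is the OLS r^2 with the two-tailed F-test p-value (for one
#' predictor this equals the two-tailed slope test); otherwise the
#' non-parametric Spearman rank correlation is used (`r_squared` = rho^2,
#' method flagged `"spearman"`).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param alpha normality-gate significance level (default 0.05).
#' @return An object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `ols_r_squared`, `p_value`, `method`
#'   (`"pearson_ols"` or `"spearman"`) and `normality_p` (the smaller of
#'   the two Shapiro-Wilk p-values).
#' @export
regression_with_normality_gate <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  fit <- stats::lm(y ~ x)
  ## collinear input triggers summary.lm's perfect-fit warning; that case
  ## is handled explicitly below
  sm <- suppressWarnings(summary(fit))
  ols_r2 <- sm$r.squared
  sw <- function(v) if (stats::sd(v) > 0) stats::shapiro.test(v)$p.value else NA_real_
  norm_p <- suppressWarnings(min(sw(x), sw(y), na.rm = TRUE))
  gate_ok <- is.finite(norm_p) && norm_p > alpha
  if (isTRUE(all.equal(ols_r2, 1))) {
    ## perfectly collinear: F statistic degenerate, p effectively 0
    p <- 0
    method <- "pearson_ols"
    r2 <- ols_r2
  } else if (gate_ok) {
    f <- sm$fstatistic
    p <- stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
    method <- "pearson_ols"
    r2 <- ols_r2
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    p <- ct$p.value
    method <- "spearman"
    r2 <- unname(ct$estimate)^2
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, ols_r_squared = ols_r2,
                 p_value = unname(p), method = method,
                 normality_p = norm_p),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s: r^2 = %.4f (OLS r^2 = %.4f), p = %.3g, slope = %.4f, intercept = %.4f\n",
              x$method, x$r_squared, x$ols_r_squared, x$p_value,
              x$slope, x$intercept))
  invisible(x)
}

#' Read a mutant energetics table
#'
#' TSV with columns `label`, `dG_ES`, `ddG_ES`, `dG_DS`, `ddG_DS`,
#' `Kd_nM`, `ddG_OBS` and optional `comparator` (reference variant for
#' the observed ddG; default "Wt"), `es_ds_comparator`, `kd_external`.
#'
#' @param path TSV file path.
#' @return data.frame of mutant records.
#' @export
read_mutant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("label", "dG_ES", "ddG_ES", "dG_DS", "ddG_DS", "Kd_nM", "ddG_OBS")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L)
    stop("mutant table lacks columns: ", paste(missing, collapse = ", "))
  if (is.null(tab$comparator)) tab$comparator <- "Wt"
  if (any(tab$Kd_nM <= 0)) stop("Kd values must be positive")
  tab
}

#' Analyse a mutant energetics table
#'
#' Recomputes the observed binding free-energy difference from the Kd
#' column for every record (honouring each record's comparator variant),
#' compares it with the printed value, and fits the three regressions of
#' interest on the printed columns: ddG_ES vs ddG_OBS (how far
#' electrostatics alone explains binding), ddG_DS vs ddG_OBS, and
#' ddG_ES vs ddG_DS (the electrostatics/desolvation opposition).
#'
#' @param records data.frame of mutant records ([read_mutant_table()] or
#'   [packaged_tables()]).
#' @param temperature absolute temperature for the Kd conversion
#'   (default 298 K).
#' @return An object of class `mutant_analysis`: list with `records` (the
#'   table plus `ddG_OBS_calc` and `ddG_OBS_diff`), `reg_es_obs`,
#'   `reg_ds_obs`, `reg_es_ds` (each a `regression_result`) and
#'   `temperature`.
#' @export
mutant_table_analysis <- function(records, temperature = 298) {
  if (is.null(records$comparator)) records$comparator <- "Wt"
  if (nrow(records) < 2L)
    stop("degenerate table: need the reference plus at least one variant")
  ref_idx <- match(records$comparator, records$label)
  if (anyNA(ref_idx))
    stop("comparator variant(s) missing from table: ",
         paste(unique(records$comparator[is.na(ref_idx)]), collapse = ", "))
  records$ddG_OBS_calc <- ddg_from_kd(records$Kd_nM,
                                      records$Kd_nM[ref_idx], temperature)
  records$ddG_OBS_diff <- records$ddG_OBS_calc - records$ddG_OBS
  structure(list(records = records,
                 reg_es_obs = regression_with_normality_gate(records$ddG_ES,
                                                             records$ddG_OBS),
                 reg_ds_obs = regression_with_normality_gate(records$ddG_DS,
                                                             records$ddG_OBS),
                 reg_es_ds = regression_with_normality_gate(records$ddG_ES,
                                                            records$ddG_DS),
                 temperature = temperature),
            class = "mutant_analysis")
}

#' @export
print.mutant_analysis <- function(x, ...) {
  cat(sprintf("mutant table analysis (%d records, T = %g K)\n",
              nrow(x$records), x$temperature))
  cat(sprintf("  max |recomputed - printed ddG_OBS| = %.2f kcal/mol\n",
              max(abs(x$records$ddG_OBS_diff))))
  cat("  ddG_ES vs ddG_OBS: "); print(x$reg_es_obs)
  cat("  ddG_DS vs ddG_OBS: "); print(x$reg_ds_obs)
  cat("  ddG_ES vs ddG_DS:  "); print(x$reg_es_ds)
  invisible(x)
}

#' Write a mutant analysis report
#'
#' @param analysis a `mutant_analysis`.
#' @param path_tsv recomputed-records TSV path.
#' @param path_txt text report path.
#' @return invisibly, the two paths.
#' @export
write_mutant_analysis <- function(analysis, path_tsv, path_txt) {
  utils::write.table(analysis$records, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(utils::capture.output(print(analysis)), path_txt)
  invisible(c(path_tsv, path_txt))
}
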