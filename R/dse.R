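## 2D-Surface-Energy (2DSE) plots.
##
## Each locus at (x, y, z) is projected onto the plane as
## (rho, z) with rho = sqrt(x^2 + y^2), i.e. its distance from the origin
## in the x-y plane against its height. Marker areas encode energetics
## through the Boltzmann-type affinity factor
##
##   area_factor = min( exp((reference_G - G) / RT), cap )
##
## so that the ratio of two (uncapped) marker areas equals the Kd ratio
## the energy difference would imply: area_i / area_j =
## exp((G_j - G_i) / RT). More negative G => exponentially larger marker.

#' Project 3D coordinates onto the (rho, z) plane
#'
#' @param xyz numeric vector of length 3, or an n x 3 matrix.
#' @return A named vector `(rho, z)`, or an n x 2 matrix.
#' @export
project_point <- function(xyz) {
  if (is.matrix(xyz)) {
    stopifnot(ncol(xyz) == 3L, all(is.finite(xyz)))
    cbind(rho = sqrt(xyz[, 1]^2 + xyz[, 2]^2), z = xyz[, 3])
  } else {
    stopifnot(length(xyz) == 3L, all(is.finite(xyz)))
    c(rho = sqrt(xyz[1]^2 + xyz[2]^2), z = xyz[3])
  }
}

#' Exponential marker-area factor for a locus energy
#'
#' @param G locus energy, kcal/mol (vectorized).
#' @param reference_G reference energy defining area 1.
#' @param RT thermal energy in kcal/mol (default 0.593, i.e. 298 K).
#' @param cap upper bound on the factor (default `exp(5)`), purely
#'   presentational: keeps a single hot spot from dominating the canvas.
#' @return area factor(s), monotone non-increasing in `G`.
#' @export
scale_marker <- function(G, reference_G, RT = 0.593, cap = exp(5)) {
  stopifnot(RT > 0, cap > 0)
  pmin(exp((reference_G - G) / RT), cap)
}

#' Build 2DSE plot data from a potential table
#'
#' @param s the `charged_structure` the table was computed from.
#' @param t a `potential_table`.
#' @param reference `"mean"` (default: area 1 is the average locus),
#'   `"least_negative"`, or an explicit numeric reference energy.
#' @param RT thermal energy, kcal/mol.
#' @param cap marker-area cap.
#' @param origin `"raw"` (use deposited file coordinates, the default) or
#'   `"centroid"` (translate the structure centroid to the origin before
#'   projecting; deposited frames are arbitrary, so both are offered).
#' @return A data.frame of class `dse_plot_data` with columns `label`,
#'   `locus_class`, `rho`, `z`, `G_ES`, `area_factor` and attributes
#'   `reference_G`, `RT`, `cap`, `structure_id`.
#' @export
build_2dse <- function(s, t, reference = "mean", RT = 0.593, cap = exp(5),
                       origin = c("raw", "centroid")) {
  origin <- match.arg(origin)
  if (nrow(t) == 0L) stop("empty potential table: nothing to plot")
  xyz <- coords(s)
  if (origin == "centroid") xyz <- sweep(xyz, 2L, colMeans(xyz))
  idx <- locus_atom_index(s, t)
  pr <- project_point(xyz[idx, , drop = FALSE])
  reference_G <- if (is.numeric(reference)) {
    reference
  } else {
    switch(match.arg(reference, c("mean", "least_negative")),
           mean = mean(t$G_ES),
           least_negative = max(t$G_ES))
  }
  out <- data.frame(label = t$label,
                    locus_class = t$locus_class,
                    rho = pr[, "rho"],
                    z = pr[, "z"],
                    G_ES = t$G_ES,
                    area_factor = scale_marker(t$G_ES, reference_G, RT, cap),
                    stringsAsFactors = FALSE)
  structure(out,
            reference_G = reference_G, RT = RT, cap = cap,
            structure_id = attr(t, "structure_id"),
            class = c("dse_plot_data", "data.frame"))
}

#' Write 2DSE plot data as TSV
#'
#' @param d a `dse_plot_data` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_2dse <- function(d, path) {
  out <- as.data.frame(d)
  names(out) <- c("locus_label", "locus_class", "rho_A", "z_A",
                  "G_ES_kcal_mol", "area_factor")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a 2DSE scatter plot
#'
#' Marker area is proportional to the exponential affinity factor, so the
#' largest spots mark the loci most conducive to binding a polyanionic
#' ligand.
#'
#' @param d a `dse_plot_data` object.
#' @param max_size largest marker size in mm (default 12).
#' @return A ggplot object.
#' @export
plot_2dse <- function(d, max_size = 12) {
  df <- as.data.frame(d)
  ggplot2::ggplot(df, ggplot2::aes(x = rho, y = z, size = area_factor)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue4") +
    ggplot2::scale_size_area(max_size = max_size, name = "affinity factor") +
    ggplot2::labs(x = expression(rho == sqrt(x^2 + y^2) ~ "(Å)"),
                  y = "z (Å)",
                  title = paste0("2DSE plot: ", attr(d, "structure_id"))) +
    ggplot2::theme_minimal()
}
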