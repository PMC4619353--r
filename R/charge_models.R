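## Residue-template charge models.
##
## Templates assign one partial charge (e) per heavy atom per residue;
## hydrogen charges are folded into their bonded heavy atom so that each
## template sums to the residue's formal charge on heavy atoms alone.
## Three models ship as TSV data files under extdata/charge_models:
##   formal      - unit charges on the charged termini of Arg/Lys/Asp/Glu
##                 sidechains, everything else zero
##   charmm-like - heavy-atom condensation of the CHARMM all-atom protein
##                 charge set
##   mmff94-like - heavy-atom template set in the spirit of MMFF94 bond
##                 increments

FORMAL_RESIDUE_CHARGE <- c(ARG = 1, LYS = 1, ASP = -1, GLU = -1)

#' Load a residue-template charge model
#'
#' @param name one of `"formal"`, `"charmm-like"`, `"mmff94-like"`, or a
#'   path to a TSV file with columns `residue_name`, `atom_name`,
#'   `charge`.
#' @param default_charge charge (e) given to atoms absent from the
#'   templates (default 0).
#' @return An object of class `charge_model`: list with `name`,
#'   `templates` (data.frame) and `default_charge`.
#' @export
charge_model <- function(name = c("formal", "charmm-like", "mmff94-like"),
                         default_charge = 0) {
  if (file.exists(name[1]) && grepl("\\.tsv$", name[1])) {
    path <- name[1]
    model_name <- sub("\\.tsv$", "", basename(path))
  } else {
    model_name <- match.arg(name)
    fname <- paste0(gsub("-", "_", model_name), ".tsv")
    path <- system.file("extdata", "charge_models", fname, package = "gbscan")
    if (path == "") stop("packaged charge model not found: ", model_name)
  }
  templates <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("residue_name", "atom_name", "charge") %in% names(templates)))
  templates$residue_name <- toupper(templates$residue_name)
  m <- structure(list(name = model_name, templates = templates,
                      default_charge = default_charge),
                 class = "charge_model")
  validate_charge_model(m)
  m
}

#' Check charge-model template sums
#'
#' Each residue template must sum to the residue's formal charge
#' (+1 Arg/Lys, -1 Asp/Glu, 0 otherwise) within 0.01 e.
#'
#' @param m a `charge_model`.
#' @return `m` invisibly; errors if a template is inconsistent.
#' @export
validate_charge_model <- function(m) {
  sums <- tapply(m$templates$charge, m$templates$residue_name, sum)
  expected <- FORMAL_RESIDUE_CHARGE[names(sums)]
  expected[is.na(expected)] <- 0
  bad <- abs(sums - expected) > 0.01
  if (any(bad))
    stop("charge model '", m$name, "': template charge sum off for ",
         paste(names(sums)[bad], collapse = ", "))
  invisible(m)
}

#' @export
print.charge_model <- function(x, ...) {
  cat(sprintf("charge_model '%s': %d residues, %d atom entries, default %.2f e\n",
              x$name, length(unique(x$templates$residue_name)),
              nrow(x$templates), x$default_charge))
  invisible(x)
}

#' Assign template partial charges to a structure
#'
#' Sets every atom's partial charge from the model's residue templates;
#' atoms without a template entry receive the model's default charge.
#' Histidine is treated as neutral by default (its protonation state near
#' physiological pH is ambiguous); `his_plus = TRUE` adds +0.5 e to each
#' of ND1 and NE2 on top of the template, modelling a doubly protonated
#' imidazolium.
#'
#' The operation is idempotent: reapplying the same model leaves charges
#' unchanged.
#'
#' @param s a cleaned `charged_structure` (heavy atoms, single conformer).
#' @param model a `charge_model` object or a model name accepted by
#'   [charge_model()].
#' @param his_plus give histidine a +1 charge (default FALSE).
#' @param strict error (instead of warn) on residues absent from the
#'   templates.
#' @return The structure with charges assigned and `charge_model` set.
#' @export
assign_charges <- function(s, model = "formal", his_plus = FALSE, strict = FALSE) {
  if (!inherits(model, "charge_model")) model <- charge_model(model)
  a <- s$atoms
  key <- paste(a$residue_name, a$name)
  tkey <- paste(model$templates$residue_name, model$templates$atom_name)
  idx <- match(key, tkey)
  q <- model$templates$charge[idx]
  q[is.na(idx)] <- model$default_charge
  known <- unique(model$templates$residue_name)
  ## formal model lists only chargeable residues; standard amino acids are
  ## implicitly zero there, not unknown
  std_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
              "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
              "TYR", "VAL")
  unknown <- setdiff(unique(a$residue_name), union(known, std_aa))
  if (length(unknown) > 0L) {
    msg <- paste("residues not in charge model templates:",
                 paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  if (his_plus) {
    his <- a$residue_name %in% c("HIS", "HSD", "HSE") & a$name %in% c("ND1", "NE2")
    q[his] <- q[his] + 0.5
  }
  out <- s
  out$atoms$partial_charge <- q
  out$charge_model <- model$name
  out
}
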