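# Model containers: subunits, assemblies, helical and Cn parameters.

#' Create a subunit model
#'
#' A subunit is an ordered atom table plus the list of residue numbers
#' flagged as glycan attachment serines.  Attachment sites must exist,
#' be serines, and own the backbone atoms N, CA, C and the side-chain
#' oxygen OG needed for frame construction.
#'
#' @param atoms Atom table (see [atom_table()]).
#' @param site_residues Integer vector of 1-based residue numbers of the
#'   attachment serines (may be empty).
#' @param validate_sites If `TRUE` (default), check the serine invariant.
#' @return An object of class `subunit_model` with components `atoms`,
#'   `site_residues` and `residue_count`.
#' @export
subunit_model <- function(atoms, site_residues = integer(0),
                          validate_sites = TRUE) {
  site_residues <- as.integer(site_residues)
  if (validate_sites) {
    for (rs in site_residues) {
      res <- atoms[atoms$res_seq == rs & !atoms$is_glycan, , drop = FALSE]
      if (nrow(res) == 0) {
        stop(sprintf("site residue %d not present in subunit", rs))
      }
      if (any(res$res_name != "SER")) {
        stop(sprintf("site residue %d is %s, not SER", rs, res$res_name[1]))
      }
      missing <- setdiff(c("N", "CA", "C", "OG"), res$name)
      if (length(missing) > 0) {
        stop(sprintf("site residue %d lacks atom(s): %s", rs,
                     paste(missing, collapse = ", ")))
      }
    }
  }
  structure(
    list(atoms = atoms,
         site_residues = site_residues,
         residue_count = count_residues(atoms)),
    class = "subunit_model"
  )
}

#' Count distinct residues in an atom table or model
#'
#' A residue is a distinct (chain_id, res_seq) pair among non-glycan
#' atoms; glycan monomers are counted separately by
#' [count_glycan_monomers()].
#'
#' @param model Atom table, `subunit_model` or `assembly_model`.
#' @return Integer residue count (summed over subunits for assemblies).
#' @export
count_residues <- function(model) {
  if (inherits(model, "assembly_model")) {
    atoms <- model$atoms
    key <- paste(atoms$subunit, atoms$chain_id, atoms$res_seq)
  } else {
    atoms <- if (is.data.frame(model)) model else model$atoms
    key <- paste(atoms$chain_id, atoms$res_seq)
  }
  prot <- !atoms$is_glycan
  length(unique(key[prot]))
}

#' Count glycan monomers in a model
#'
#' Each glycan monomer is one glycan residue (distinct subunit, chain,
#' res_seq among glycan-flagged atoms).
#'
#' @param model Atom table, `subunit_model` or `assembly_model`.
#' @return Integer monomer count.
#' @export
count_glycan_monomers <- function(model) {
  if (inherits(model, "assembly_model")) {
    atoms <- model$atoms
    key <- paste(atoms$subunit, atoms$chain_id, atoms$res_seq)
  } else {
    atoms <- if (is.data.frame(model)) model else model$atoms
    key <- paste(atoms$chain_id, atoms$res_seq)
  }
  length(unique(key[atoms$is_glycan]))
}

#' Create an assembly model
#'
#' An assembly holds the atoms of several transformed subunit copies in a
#' single table with a `subunit` index column.  The assembly axis is by
#' convention +z through the origin; inputs must be pre-aligned (see
#' [align_to_axis()]).
#'
#' @param atoms Atom table with an integer `subunit` column.
#' @param kind One of `"filament"`, `"ring"`, `"channel"`.
#' @param site_residues Attachment site residue numbers, valid in every
#'   subunit (filament/ring kinds).
#' @return Object of class `assembly_model`.
#' @export
assembly_model <- function(atoms, kind = c("filament", "ring", "channel"),
                           site_residues = integer(0)) {
  kind <- match.arg(kind)
  if (is.null(atoms$subunit)) atoms$subunit <- 1L
  n_sub <- length(unique(atoms$subunit))
  if (kind %in% c("filament", "ring") && n_sub > 1) {
    counts <- table(atoms$subunit[!atoms$is_glycan])
    if (length(unique(as.integer(counts))) > 1) {
      stop("subunit atom counts differ across subunits")
    }
  }
  structure(
    list(atoms = atoms, kind = kind, n_subunits = n_sub,
         site_residues = as.integer(site_residues)),
    class = "assembly_model"
  )
}

#' @export
print.subunit_model <- function(x, ...) {
  cat(sprintf("<subunit_model> %d atoms, %d residues, sites: %s\n",
              nrow(x$atoms), x$residue_count,
              if (length(x$site_residues)) {
                paste(x$site_residues, collapse = ", ")
              } else "none"))
  invisible(x)
}

#' @export
print.assembly_model <- function(x, ...) {
  cat(sprintf(
    "<assembly_model kind=%s> %d subunits, %d atoms, %d residues, %d glycan monomers\n",
    x$kind, x$n_subunits, nrow(x$atoms), count_residues(x),
    count_glycan_monomers(x)))
  invisible(x)
}

#' Helical symmetry parameters
#'
#' Twist (degrees per subunit, signed; positive = right-handed rotation
#' about +z) and rise (Angstrom per subunit, positive).
#'
#' @param twist_deg Signed twist, |twist| <= 180.
#' @param rise_A Positive rise in Angstrom.
#' @return Object of class `helical_params`.
#' @export
helical_params <- function(twist_deg, rise_A) {
  if (abs(twist_deg) > 180) stop("|twist_deg| must be <= 180")
  if (!(rise_A > 0)) stop("rise_A must be positive")
  structure(list(twist_deg = twist_deg, rise_A = rise_A),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("<helical_params> twist %.4g deg, rise %.4g A\n",
              x$twist_deg, x$rise_A))
  invisible(x)
}

#' Cn point-group parameters
#'
#' @param order Integer n >= 1; the rotational step is 360/n degrees.
#' @return Object of class `cn_params` with `order` and `step_deg`.
#' @export
cn_params <- function(order) {
  order <- as.integer(order)
  if (is.na(order) || order < 1) stop("Cn order must be a positive integer")
  structure(list(order = order, step_deg = 360 / order), class = "cn_params")
}

#' Display string for a Cn rotational step, rounded to one decimal
#'
#' @param params A `cn_params` object.
#' @return Character string, e.g. `"27.7"` for C13.
#' @export
cn_step_display <- function(params) {
  sprintf("%.1f", round(params$step_deg, 1))
}

#' @export
print.cn_params <- function(x, ...) {
  cat(sprintf("<cn_params> C%d, step %s deg\n", x$order, cn_step_display(x)))
  invisible(x)
}
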