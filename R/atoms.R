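# Atom tables: the flat coordinate representation shared by all stages.
#
# Atoms are rows of a data.frame with fixed columns; models (subunits,
# assemblies, conformer libraries) wrap these tables.  Coordinates are in
# Angstrom throughout and the filament/channel axis is +z through the origin.

#' Glycan residue codes and their PDB residue names
#'
#' The pipeline models four monosaccharide types: `N` (alpha-GalNAc,
#' N-acetylgalactosamine), `H` (hexose, assigned as alpha-mannose), `W`
#' (the pseudaminic-acid derivative 5Am7Ac) and `X` (an unassigned
#' monosaccharide of 346 Da).  Each code maps to a three-letter residue
#' name used in PDB output; names are chosen to avoid collision with
#' standard amino-acid codes.
#'
#' @return Named character vector mapping code to residue name.
#' @export
glycan_res_names <- function() {
  c(W = "SUW", H = "SUH", N = "SUN", X = "SUX")
}

#' @keywords internal
atom_cols <- function() {
  c("serial", "name", "element", "res_name", "res_seq", "chain_id",
    "x", "y", "z", "is_glycan", "is_alpha_carbon", "is_ring_oxygen")
}

#' Construct an atom table
#'
#' Builds the canonical atom data.frame used inside all model objects and
#' derives the role flags (`is_alpha_carbon`, `is_ring_oxygen`) from the
#' atom and residue names.  An alpha carbon is a non-glycan atom named
#' `"CA"`; a ring oxygen is a glycan atom named `"O5"` (the glycan builder
#' places exactly one per monomer).
#'
#' @param serial Integer atom serial numbers.
#' @param name Atom name strings (e.g. `"CA"`, `"OG"`, `"O5"`).
#' @param element Element symbols; derived from the first letter of the
#'   atom name when missing.
#' @param res_name Three-letter residue / monomer codes.
#' @param res_seq 1-based residue numbers.
#' @param chain_id Single-character chain identifiers.
#' @param coord Numeric matrix with 3 columns (x, y, z), Angstrom.
#' @param is_glycan Logical flag per atom; defaults to membership of
#'   `res_name` in [glycan_res_names()].
#' @return A data.frame with one row per atom.
#' @export
atom_table <- function(serial, name, element = NULL, res_name, res_seq,
                       chain_id, coord, is_glycan = NULL) {
  coord <- matrix(as.numeric(coord), ncol = 3)
  n <- nrow(coord)
  if (n > 0 && !all(is.finite(coord))) {
    stop("atom coordinates must be finite")
  }
  if (is.null(is_glycan)) {
    is_glycan <- res_name %in% glycan_res_names()
  }
  if (is.null(element)) {
    element <- toupper(substr(gsub("[0-9]", "", name), 1, 1))
  }
  df <- data.frame(
    serial = as.integer(serial),
    name = as.character(name),
    element = as.character(element),
    res_name = as.character(res_name),
    res_seq = as.integer(res_seq),
    chain_id = as.character(chain_id),
    x = coord[, 1], y = coord[, 2], z = coord[, 3],
    is_glycan = as.logical(is_glycan),
    stringsAsFactors = FALSE
  )
  derive_roles(df)
}

#' @keywords internal
derive_roles <- function(df) {
  df$is_alpha_carbon <- df$name == "CA" & !df$is_glycan
  df$is_ring_oxygen <- df$name == "O5" & df$is_glycan
  df
}

#' @keywords internal
empty_atom_table <- function() {
  atom_table(integer(0), character(0), character(0), character(0),
             integer(0), character(0), matrix(numeric(0), ncol = 3),
             logical(0))
}

#' Extract atom coordinates as a matrix
#'
#' @param atoms Atom table (or a model with an `$atoms` component).
#' @return n x 3 numeric matrix.
#' @export
coords <- function(atoms) {
  if (!is.data.frame(atoms)) atoms <- atoms$atoms
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

#' @keywords internal
set_coords <- function(atoms, m) {
  atoms$x <- m[, 1]; atoms$y <- m[, 2]; atoms$z <- m[, 3]
  atoms
}

#' Select atoms by structural role
#'
#' Roles partition the model: `protein` and `glycan` are disjoint and
#' together cover every atom; `alpha_carbons` is a subset of `protein`
#' and `ring_oxygens` a subset of `glycan`.  Row order is preserved.
#'
#' @param model A `subunit_model`, `assembly_model`, or bare atom table.
#' @param role One of `"alpha_carbons"`, `"ring_oxygens"`, `"glycan"`,
#'   `"protein"`.
#' @return Atom table containing the selected rows.
#' @export
select_atoms <- function(model, role = c("alpha_carbons", "ring_oxygens",
                                         "glycan", "protein")) {
  role <- match.arg(role)
  atoms <- if (is.data.frame(model)) model else model$atoms
  if (nrow(atoms) == 0) stop("select_atoms: model has no atoms")
  keep <- switch(role,
    alpha_carbons = atoms$is_alpha_carbon,
    ring_oxygens = atoms$is_ring_oxygen,
    glycan = atoms$is_glycan,
    protein = !atoms$is_glycan
  )
  atoms[keep, , drop = FALSE]
}
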