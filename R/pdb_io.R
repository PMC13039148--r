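# Strict fixed-column PDB v3.3 subset reader/writer.
#
# Supported records: ATOM, HETATM, MODEL, ENDMDL, TER, END.  Glycan atoms
# are written as HETATM; occupancy/B-factor are fixed at 1.00/0.00; the
# element column is populated.  Output is byte-deterministic for a given
# model.  Not supported (out of scope): mmCIF, altlocs, insertion codes,
# anisotropic records, occupancy handling.

#' @keywords internal
format_atom_line <- function(record, serial, name, res_name, chain_id,
                             res_seq, x, y, z, element) {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, res_name, chain_id, res_seq,
          x, y, z, 1.0, 0.0, element)
}

#' @keywords internal
atom_block_lines <- function(atoms, ter_breaks = TRUE) {
  n <- nrow(atoms)
  if (n == 0) return(character(0))
  bad <- atoms$x < -999.999 | atoms$x > 9999.999 |
    atoms$y < -999.999 | atoms$y > 9999.999 |
    atoms$z < -999.999 | atoms$z > 9999.999
  if (any(bad)) {
    stop(sprintf("coordinate overflow: %d atom(s) outside the PDB %%8.3f range",
                 sum(bad)))
  }
  sub <- if (is.null(atoms$subunit)) rep(1L, n) else atoms$subunit
  block <- cumsum(c(TRUE, sub[-1] != sub[-n] |
                            atoms$chain_id[-1] != atoms$chain_id[-n]))
  lines <- character(0)
  serial <- 0L
  for (b in unique(block)) {
    rows <- which(block == b)
    for (i in rows) {
      serial <- serial + 1L
      rec <- if (atoms$is_glycan[i]) "HETATM" else "ATOM"
      lines <- c(lines, format_atom_line(
        rec, serial, atoms$name[i], atoms$res_name[i], atoms$chain_id[i],
        atoms$res_seq[i], atoms$x[i], atoms$y[i], atoms$z[i],
        atoms$element[i]))
    }
    if (ter_breaks) lines <- c(lines, "TER")
  }
  lines
}

#' Write a model to a PDB file
#'
#' Subunit and assembly models are written as TER-separated chain blocks;
#' conformer libraries as MODEL/ENDMDL blocks.  Serial numbers are
#' renumbered sequentially.  Writing the same model twice produces
#' byte-identical files.
#'
#' @param model `subunit_model`, `assembly_model`, `conformer_library`,
#'   or a bare atom table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  lines <- if (inherits(model, "conformer_library")) {
    unlist(lapply(seq_along(model$frames), function(i) {
      c(sprintf("MODEL     %4d", i),
        atom_block_lines(model$frames[[i]], ter_breaks = FALSE),
        "ENDMDL")
    }))
  } else {
    atoms <- if (is.data.frame(model)) model else model$atoms
    atom_block_lines(atoms)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(lines, "END"), con, sep = "\n")
  invisible(path)
}

#' @keywords internal
parse_fixed_num <- function(s, lineno, what, integer = FALSE) {
  s <- trimws(s)
  v <- suppressWarnings(if (integer) as.integer(s) else as.numeric(s))
  if (length(v) == 0 || is.na(v)) {
    stop(sprintf("PDB parse error at line %d: malformed %s field '%s'",
                 lineno, what, s))
  }
  v
}

#' Read a PDB-subset file
#'
#' Parses ATOM/HETATM/MODEL/ENDMDL/TER/END records at fixed column
#' positions.  The return type depends on the file layout:
#' \itemize{
#'   \item multiple MODEL blocks: a list of atom tables (one per model)
#'     with class `pdb_frames`, suitable for [conformer_library()];
#'   \item a single model with several TER-separated chain blocks: an
#'     [assembly_model()];
#'   \item otherwise a [subunit_model()] (site residues left empty; use
#'     [subunit_model()] to re-declare them).
#' }
#' Role flags are derived from names: `is_glycan` by `res_name`
#' membership in `glycan_names`, `is_alpha_carbon` for non-glycan `"CA"`,
#' `is_ring_oxygen` for glycan `"O5"`.
#'
#' @param path Input file path.
#' @param glycan_names Residue names treated as glycan monomers; defaults
#'   to [glycan_res_names()].  Extend when loading externally deposited
#'   glycans with other monomer codes.
#' @return See Details.
#' @export
read_pdb <- function(path, glycan_names = glycan_res_names()) {
  if (!file.exists(path)) stop(sprintf("cannot read PDB file: %s", path))
  lines <- readLines(path)
  frames <- list()
  cur <- list(serial = integer(0), name = character(0),
              element = character(0), res_name = character(0),
              res_seq = integer(0), chain = character(0),
              xyz = list(), block = integer(0))
  block_id <- 1L
  saw_atoms <- FALSE
  in_model <- FALSE
  n_models <- 0L

  flush_frame <- function(cur) {
    xyz <- do.call(rbind, cur$xyz)
    at <- atom_table(cur$serial, cur$name, cur$element, cur$res_name,
                     cur$res_seq, cur$chain, xyz,
                     is_glycan = cur$res_name %in% glycan_names)
    at$subunit <- cur$block
    if (anyDuplicated(at$serial)) {
      warning("duplicate atom serial numbers; renumbering sequentially")
      at$serial <- seq_len(nrow(at))
    }
    at
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    rec <- trimws(substr(ln, 1, 6))
    if (rec == "MODEL") {
      in_model <- TRUE
      n_models <- n_models + 1L
    } else if (rec == "ENDMDL") {
      frames[[length(frames) + 1L]] <- flush_frame(cur)
      cur <- list(serial = integer(0), name = character(0),
                  element = character(0), res_name = character(0),
                  res_seq = integer(0), chain = character(0),
                  xyz = list(), block = integer(0))
      block_id <- 1L
    } else if (rec == "TER") {
      block_id <- block_id + 1L
    } else if (rec %in% c("ATOM", "HETATM")) {
      if (nchar(ln) < 54) {
        stop(sprintf("PDB parse error at line %d: record too short", i))
      }
      saw_atoms <- TRUE
      k <- length(cur$serial) + 1L
      cur$serial[k] <- parse_fixed_num(substr(ln, 7, 11), i, "serial", TRUE)
      cur$name[k] <- trimws(substr(ln, 13, 16))
      cur$res_name[k] <- trimws(substr(ln, 18, 20))
      cur$chain[k] <- trimws(substr(ln, 22, 22))
      cur$res_seq[k] <- parse_fixed_num(substr(ln, 23, 26), i, "res_seq", TRUE)
      cur$xyz[[k]] <- c(parse_fixed_num(substr(ln, 31, 38), i, "x"),
                        parse_fixed_num(substr(ln, 39, 46), i, "y"),
                        parse_fixed_num(substr(ln, 47, 54), i, "z"))
      el <- trimws(substr(ln, 77, 78))
      cur$element[k] <- if (nzchar(el)) el else
        toupper(substr(gsub("[0-9]", "", cur$name[k]), 1, 1))
      cur$block[k] <- block_id
    }
  }
  if (!saw_atoms && length(frames) == 0) {
    stop(sprintf("no ATOM/HETATM records found in '%s'", path))
  }
  if (length(cur$serial) > 0) frames[[length(frames) + 1L]] <- flush_frame(cur)

  if (n_models > 1) {
    return(structure(frames, class = "pdb_frames"))
  }
  at <- frames[[1]]
  blocks <- unique(at$subunit)
  if (length(blocks) > 1) {
    at$subunit <- match(at$subunit, blocks)
    counts <- table(at$subunit[!at$is_glycan])
    kind <- if (length(unique(as.integer(counts))) == 1) "filament" else "channel"
    return(assembly_model(at, kind = kind))
  }
  at$subunit <- NULL
  subunit_model(at)
}
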