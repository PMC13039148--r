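# Glycan topologies, idealized chain building, attachment frames and
# rigid conformer grafting.
#
# Monomer geometry is deliberately idealized: each monosaccharide is a
# planar hexagon of radius 1.4 A (five carbons plus the ring oxygen
# "O5") with a glycosidic link pseudo-atom "O1" 1.43 A from the monomer
# centre, consecutive monomer centres ~5 A apart.  The steric analysis
# downstream depends only on ring-oxygen positions, so this level of
# detail is sufficient and is documented as such.

#' Glycan chain topology
#'
#' Ordered monomer codes written from the non-reducing end, as in
#' W-H-N-N-(Ser): the last code in `monomers` is the serine-linked
#' monomer.  Codes: `W` = 5Am7Ac (pseudaminic-acid derivative), `H` =
#' hexose (Man), `N` = GalNAc, `X` = unknown 346 Da monosaccharide.
#'
#' @param monomers Character vector of 1 to 4 codes from W/H/N/X.
#' @param linkages Per-junction linkage labels, length
#'   `length(monomers) - 1` (e.g. `"a(1-4)"`); informational only — the
#'   idealized geometry is linkage-agnostic.
#' @param attachment Attachment label, default `"a-Ser"`.
#' @return Object of class `glycan_topology`.
#' @export
glycan_topology <- function(monomers, linkages = NULL, attachment = "a-Ser") {
  monomers <- as.character(monomers)
  if (length(monomers) < 1 || length(monomers) > 4) {
    stop("glycan chains have 1 to 4 monomers")
  }
  bad <- setdiff(monomers, c("W", "H", "N", "X"))
  if (length(bad) > 0) {
    stop(sprintf("unknown monomer code(s): %s", paste(bad, collapse = ", ")))
  }
  if (is.null(linkages)) {
    linkages <- rep("a(1-3)", max(0L, length(monomers) - 1L))
  }
  if (length(monomers) >= 2 && length(linkages) != length(monomers) - 1) {
    stop("need one linkage label per junction")
  }
  structure(list(monomers = monomers, linkages = linkages,
                 attachment = attachment),
            class = "glycan_topology")
}

#' O-glycosylation site maps
#'
#' The built-in maps reproduce the observed decoration of the two
#' filament forms: the wide filament carries a trisaccharide H-N-N at
#' S59, a single GalNAc at S66 and the tetrasaccharide W-H-N-N at S71
#' (8 monomers per subunit); the narrow filament carries the W-H-N-N
#' tetrasaccharide at its single site S73 (4 monomers per subunit).
#'
#' @param name `"wide"`, `"narrow"`, or `"custom"` (then supply
#'   `entries`).
#' @param entries For `"custom"`: named list mapping residue numbers
#'   (as names) to [glycan_topology()] objects.
#' @return Object of class `site_map`: list with `name` and `entries`.
#' @export
site_map <- function(name = c("wide", "narrow", "custom"), entries = NULL) {
  name <- match.arg(name)
  if (name == "wide") {
    entries <- list(
      `59` = glycan_topology(c("H", "N", "N"), c("a(1-4)", "a(1-3)")),
      `66` = glycan_topology("N"),
      `71` = glycan_topology(c("W", "H", "N", "N"),
                             c("a(1-4)", "a(1-3)", "a(1-3)"))
    )
  } else if (name == "narrow") {
    entries <- list(
      `73` = glycan_topology(c("W", "H", "N", "N"),
                             c("a(1-4)", "a(1-3)", "a(1-3)"))
    )
  } else if (is.null(entries)) {
    entries <- list()
  }
  structure(list(name = name, entries = entries), class = "site_map")
}

#' Residue numbers of a site map
#' @param map A `site_map`.
#' @return Integer vector of attachment residue numbers.
#' @export
site_map_residues <- function(map) as.integer(names(map$entries))

#' Total glycan monomers per subunit under a site map
#' @param map A `site_map`.
#' @return Integer monomer count summed over sites.
#' @export
site_map_monomers <- function(map) {
  sum(vapply(map$entries, function(e) length(e$monomers), integer(1)))
}

#' Idealized serine O-gamma position in the local attachment frame
#'
#' Glycan chains and sampled conformers are anchored at this fixed
#' offset (2.4 A from the alpha carbon, the canonical CA-OG distance in
#' serine), expressed in the frame of [attachment_frame()].
#'
#' @return Numeric 3-vector, Angstrom.
#' @export
serine_og_offset <- function() c(0, 1.92, 1.44)

#' @keywords internal
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' @keywords internal
perp_basis <- function(u) {
  # deterministic orthonormal completion of a unit vector
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- unit3(c(u[2] * ref[3] - u[3] * ref[2],
               u[3] * ref[1] - u[1] * ref[3],
               u[1] * ref[2] - u[2] * ref[1]))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  cbind(v, w)
}

#' @keywords internal
monomer_template_atoms <- function(center, dir, res_name, res_seq,
                                   chain_id = "G") {
  vw <- perp_basis(unit3(dir))
  ang <- seq(0, 300, by = 60) * pi / 180
  ring <- t(vapply(ang, function(a) {
    center + 1.4 * (cos(a) * vw[, 1] + sin(a) * vw[, 2])
  }, numeric(3)))
  link <- center - 1.43 * unit3(dir)
  xyz <- rbind(ring, link)
  nm <- c("O5", "C1", "C2", "C3", "C4", "C5", "O1")
  atom_table(seq_len(7), nm,
             c("O", "C", "C", "C", "C", "C", "O"),
             rep(res_name, 7), rep(res_seq, 7), rep(chain_id, 7),
             xyz, is_glycan = rep(TRUE, 7))
}

#' Build an idealized glycan chain in the local attachment frame
#'
#' The chain grows from the serine end: the first placed monomer is the
#' Ser-linked one (the last code in the topology), anchored at the
#' O-gamma offset, with successive monomer centres spaced
#' `step_length_A` along a fixed outward direction.  Each monomer is the
#' hexagon template with exactly one ring oxygen `"O5"`.
#'
#' @param topology A [glycan_topology()], or NULL for an empty chain.
#' @param step_length_A Centre-to-centre spacing, default 5 A.
#' @return Atom table in local-frame coordinates (empty for NULL
#'   topology); residue numbers run 1..n from the serine end.
#' @export
build_glycan_chain <- function(topology, step_length_A = 5) {
  if (is.null(topology)) return(empty_atom_table())
  stopifnot(inherits(topology, "glycan_topology"))
  codes <- rev(topology$monomers)  # serine end first
  og <- serine_og_offset()
  d0 <- unit3(og)
  res_names <- glycan_res_names()[codes]
  pieces <- lapply(seq_along(codes), function(k) {
    center <- og + (2.5 + (k - 1) * step_length_A) * d0
    monomer_template_atoms(center, d0, res_names[[k]], k)
  })
  at <- do.call(rbind, pieces)
  at$serial <- seq_len(nrow(at))
  at
}

#' Local attachment frame of a serine residue
#'
#' Right-handed orthonormal frame built from the backbone: origin at the
#' alpha carbon; `e1` along CA->N; `e2` the Gram-Schmidt
#' orthogonalization of CA->C against `e1`; `e3 = e1 x e2`.
#'
#' @param subunit `subunit_model` or atom table.
#' @param res_seq Residue number of the attachment serine.
#' @param subunit_index For assembly atom tables: restrict to this
#'   subunit (default all rows).
#' @return Object of class `attachment_frame`: `origin`, `e1`, `e2`,
#'   `e3`, and the 3x3 basis matrix `R = cbind(e1, e2, e3)`.
#' @export
attachment_frame <- function(subunit, res_seq, subunit_index = NULL) {
  atoms <- if (is.data.frame(subunit)) subunit else subunit$atoms
  if (!is.null(subunit_index) && !is.null(atoms$subunit)) {
    atoms <- atoms[atoms$subunit == subunit_index, , drop = FALSE]
  }
  res <- atoms[atoms$res_seq == res_seq & !atoms$is_glycan, , drop = FALSE]
  if (nrow(res) == 0) stop(sprintf("residue %d not found", res_seq))
  get1 <- function(nm) {
    i <- which(res$name == nm)
    if (length(i) == 0) {
      stop(sprintf("residue %d is missing backbone atom %s", res_seq, nm))
    }
    c(res$x[i[1]], res$y[i[1]], res$z[i[1]])
  }
  ca <- get1("CA"); nn <- get1("N"); cc <- get1("C")
  e1 <- unit3(nn - ca)
  v <- cc - ca
  e2v <- v - sum(v * e1) * e1
  if (sqrt(sum(e2v^2)) < 1e-9) {
    stop(sprintf("degenerate backbone geometry at residue %d", res_seq))
  }
  e2 <- unit3(e2v)
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  structure(list(origin = ca, e1 = e1, e2 = e2, e3 = e3,
                 R = cbind(e1, e2, e3)),
            class = "attachment_frame")
}

#' Graft local-frame glycan coordinates into assembly coordinates
#'
#' Rigid placement: `x_global = origin + e1*x + e2*y + e3*z` per atom.
#' Distances within the conformer are preserved exactly.
#'
#' @param conformer Atom table (or bare n x 3 matrix) in the local
#'   attachment frame.
#' @param frame An [attachment_frame()].
#' @return Same type as `conformer`, with transformed coordinates.
#' @export
graft_conformer <- function(conformer, frame) {
  stopifnot(inherits(frame, "attachment_frame"))
  if (is.matrix(conformer)) {
    return(sweep(conformer %*% t(frame$R), 2, frame$origin, "+"))
  }
  m <- coords(conformer) %*% t(frame$R)
  set_coords(conformer, sweep(m, 2, frame$origin, "+"))
}

#' Conformer library
#'
#' A set of M glycan conformations expressed in the local attachment
#' frame, ready for rigid grafting.  All frames must share atom count
#' and naming, and each monomer must contribute at least one ring
#' oxygen.
#'
#' @param frames List of atom tables (or a `pdb_frames` object from
#'   [read_pdb()]).
#' @param topology Optional [glycan_topology()].
#' @param seed Optional integer seed recorded for provenance.
#' @return Object of class `conformer_library` with `frames`,
#'   `n_conformers`, `topology`, `seed`.
#' @export
conformer_library <- function(frames, topology = NULL, seed = NULL) {
  frames <- unclass(frames)
  if (length(frames) < 1) stop("conformer library must be non-empty")
  ref <- frames[[1]]
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (nrow(f) != nrow(ref) || !identical(f$name, ref$name)) {
      stop(sprintf("conformer %d differs in atom count or naming", i))
    }
    n_mono <- length(unique(f$res_seq[f$is_glycan]))
    n_ring <- sum(f$is_ring_oxygen)
    if (n_ring < n_mono) {
      stop(sprintf("conformer %d has %d ring oxygens for %d monomers",
                   i, n_ring, n_mono))
    }
  }
  structure(list(frames = frames, n_conformers = length(frames),
                 topology = topology, seed = seed),
            class = "conformer_library")
}

#' @export
print.conformer_library <- function(x, ...) {
  cat(sprintf("<conformer_library> %d conformers, %d atoms each%s\n",
              x$n_conformers, nrow(x$frames[[1]]),
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  invisible(x)
}

#' Decorate a filament with glycans at its attachment sites
#'
#' In `static_chain` mode every site of every subunit receives the
#' idealized straight chain for its topology; in `library` mode a
#' conformer is drawn (seeded, uniformly) from the site's library for
#' each subunit.  Glycan residues are numbered after the last protein
#' residue of each subunit and inherit the subunit chain identifier.
#'
#' @param filament An `assembly_model` (or `subunit_model`).
#' @param map A [site_map()].
#' @param mode `"static_chain"` (default) or `"library"`.
#' @param libraries For `"library"` mode: a single [conformer_library()]
#'   used at every site, or a named list keyed by residue number.
#' @param seed Seed for library-mode conformer draws.
#' @return The decorated model (same class), with glycan atoms flagged.
#' @export
decorate_assembly <- function(filament, map,
                              mode = c("static_chain", "library"),
                              libraries = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "site_map"))
  single <- inherits(filament, "subunit_model")
  atoms <- filament$atoms
  if (is.null(atoms$subunit)) atoms$subunit <- 1L
  res_seqs <- site_map_residues(map)
  if (length(res_seqs) == 0) return(filament)
  subs <- sort(unique(atoms$subunit))
  lib_for <- function(rs) {
    if (inherits(libraries, "conformer_library")) return(libraries)
    lib <- libraries[[as.character(rs)]]
    if (is.null(lib)) stop(sprintf("no conformer library for site %d", rs))
    lib
  }
  out <- list(atoms)
  draw <- NULL
  if (mode == "library") {
    draw <- with_seed(seed, {
      matrix(stats::runif(length(subs) * length(res_seqs)),
             nrow = length(subs))
    })
  }
  for (si in seq_along(subs)) {
    sub_atoms <- atoms[atoms$subunit == subs[si], , drop = FALSE]
    chain <- sub_atoms$chain_id[1]
    next_res <- max(sub_atoms$res_seq) + 1L
    for (ri in seq_along(res_seqs)) {
      rs <- res_seqs[ri]
      topo <- map$entries[[as.character(rs)]]
      fr <- attachment_frame(sub_atoms, rs)
      local_at <- if (mode == "static_chain") {
        build_glycan_chain(topo)
      } else {
        lib <- lib_for(rs)
        idx <- 1L + as.integer(floor(draw[si, ri] * lib$n_conformers))
        idx <- min(idx, lib$n_conformers)
        lib$frames[[idx]]
      }
      g <- graft_conformer(local_at, fr)
      g$res_seq <- next_res - 1L + match(g$res_seq, sort(unique(g$res_seq)))
      next_res <- max(g$res_seq) + 1L
      g$chain_id <- chain
      g$subunit <- subs[si]
      out[[length(out) + 1L]] <- g
    }
  }
  all_atoms <- do.call(rbind, out)
  # stable sort: protein atoms of each subunit precede its glycans
  all_atoms <- all_atoms[order(all_atoms$subunit), , drop = FALSE]
  all_atoms$serial <- seq_len(nrow(all_atoms))
  if (single) {
    all_atoms$subunit <- NULL
    m <- subunit_model(all_atoms, filament$site_residues)
    return(m)
  }
  assembly_model(all_atoms, kind = filament$kind,
                 site_residues = res_seqs)
}
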