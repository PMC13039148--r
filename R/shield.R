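# Steric accommodation of grafted glycan conformers: accept/reject per
# conformer against an environment, per-site acceptance fractions,
# axially binned rejection profiles, and channel aperture profiles.

#' Steric grafting criterion
#'
#' A grafted conformer is accepted iff the minimum distance between its
#' selected glycan atoms and the selected environment (protein) atoms is
#' greater than or equal to `threshold_A`.  The default pairing is
#' protein alpha carbons against glycan ring oxygens, with thresholds of
#' 3.25 A (mimicking lower filament stiffness) or 3.75 A (higher
#' stiffness) as the two standard settings.  Distance exactly at the
#' threshold counts as accepted.
#'
#' @param threshold_A Positive grafting threshold in Angstrom.
#' @param glycan_atoms `"ring_oxygens"` (default) or `"all"`.
#' @param protein_atoms `"alpha_carbons"` (default) or `"all"`.
#' @param exclude_attachment Exclude the attachment residue's own atoms
#'   from the environment of its site (they are always within bonded
#'   distance of the first monomer).  Default TRUE.
#' @return Object of class `steric_criterion`.
#' @export
steric_criterion <- function(threshold_A = 3.25,
                             glycan_atoms = c("ring_oxygens", "all"),
                             protein_atoms = c("alpha_carbons", "all"),
                             exclude_attachment = TRUE) {
  if (!(threshold_A > 0)) stop("threshold_A must be positive")
  structure(list(threshold_A = threshold_A,
                 glycan_atoms = match.arg(glycan_atoms),
                 protein_atoms = match.arg(protein_atoms),
                 exclude_attachment = isTRUE(exclude_attachment)),
            class = "steric_criterion")
}

#' @keywords internal
criterion_glycan_coords <- function(conformer, criterion) {
  if (is.matrix(conformer)) return(conformer)
  keep <- if (criterion$glycan_atoms == "ring_oxygens") {
    conformer$is_ring_oxygen
  } else {
    conformer$is_glycan
  }
  coords(conformer[keep, , drop = FALSE])
}

#' @keywords internal
criterion_env_coords <- function(environment, criterion) {
  if (is.matrix(environment)) return(environment)
  atoms <- if (is.data.frame(environment)) environment else environment$atoms
  keep <- if (criterion$protein_atoms == "alpha_carbons") {
    atoms$is_alpha_carbon
  } else {
    !atoms$is_glycan
  }
  coords(atoms[keep, , drop = FALSE])
}

#' @keywords internal
min_pair_dist2 <- function(G, E) {
  best <- Inf
  for (i in seq_len(nrow(G))) {
    d2 <- (E[, 1] - G[i, 1])^2 + (E[, 2] - G[i, 2])^2 + (E[, 3] - G[i, 3])^2
    m <- min(d2)
    if (m < best) best <- m
  }
  best
}

#' Steric accept/reject decision for one grafted conformer
#'
#' Accepted iff the minimum glycan-environment pairwise distance is >=
#' the threshold.  The implementation prunes the environment with an
#' axis-aligned bounding box expanded by the threshold before computing
#' distances; any pair closer than the threshold necessarily survives
#' the pruning, so decisions (and the reported minimum, when rejected)
#' are identical to an all-pairs evaluation.
#'
#' @param conformer Grafted conformer: atom table or n x 3 coordinate
#'   matrix (matrices are used as-is; tables are filtered per the
#'   criterion's glycan selection).
#' @param environment Environment atoms: atom table, model, or
#'   coordinate matrix (tables are filtered per the criterion's protein
#'   selection).
#' @param criterion A [steric_criterion()].
#' @return List with `accepted` (logical) and `min_distance_A` (exact
#'   minimum pairwise distance; `Inf` when either selection is empty).
#' @export
steric_accept <- function(conformer, environment, criterion = steric_criterion()) {
  G <- criterion_glycan_coords(conformer, criterion)
  E <- criterion_env_coords(environment, criterion)
  if (nrow(G) == 0 || nrow(E) == 0) {
    return(list(accepted = TRUE, min_distance_A = Inf))
  }
  thr <- criterion$threshold_A
  lo <- c(min(G[, 1]), min(G[, 2]), min(G[, 3])) - thr
  hi <- c(max(G[, 1]), max(G[, 2]), max(G[, 3])) + thr
  near <- E[, 1] >= lo[1] & E[, 1] <= hi[1] &
    E[, 2] >= lo[2] & E[, 2] <= hi[2] &
    E[, 3] >= lo[3] & E[, 3] <= hi[3]
  if (any(near)) {
    d2 <- min_pair_dist2(G, E[near, , drop = FALSE])
    if (d2 < thr^2) {
      return(list(accepted = FALSE, min_distance_A = sqrt(d2)))
    }
  }
  # accepted: report the exact global minimum
  list(accepted = TRUE, min_distance_A = sqrt(min_pair_dist2(G, E)))
}

#' @keywords internal
site_environment <- function(assembly, environment, criterion,
                             subunit_index, res_seq) {
  atoms <- assembly$atoms
  keep <- if (criterion$protein_atoms == "alpha_carbons") {
    atoms$is_alpha_carbon
  } else {
    !atoms$is_glycan
  }
  if (criterion$exclude_attachment) {
    own <- atoms$subunit == subunit_index & atoms$res_seq == res_seq &
      !atoms$is_glycan
    keep <- keep & !own
  }
  E <- coords(atoms[keep, , drop = FALSE])
  if (!is.null(environment)) {
    E <- rbind(E, criterion_env_coords(environment, criterion))
  }
  E
}

#' Acceptance statistics for one attachment site
#'
#' Grafts (a subsample of) a conformer library at the given site's
#' attachment frame and evaluates [steric_accept()] for each conformer
#' against the assembly plus any extra environment (e.g. a channel).
#' Subsampling is seeded and without replacement.
#'
#' @param assembly `assembly_model` carrying the site (aligned to +z).
#' @param subunit_index Subunit holding the site.
#' @param res_seq Attachment serine residue number.
#' @param library A [conformer_library()].
#' @param criterion A [steric_criterion()].
#' @param environment Optional additional environment (model, atom table
#'   or coordinate matrix), e.g. the channel the filament is docked in.
#' @param subsample Number of conformers to evaluate; default
#'   `min(M, 1000)`.
#' @param seed Subsampling seed (default 1).
#' @return List: `accepted`, `total`, `fraction`, `z_A` (axial
#'   coordinate of the grafting anchor), `subunit`, `res_seq`.
#' @export
site_acceptance <- function(assembly, subunit_index, res_seq, library,
                            criterion = steric_criterion(),
                            environment = NULL,
                            subsample = NULL, seed = 1L) {
  stopifnot(inherits(library, "conformer_library"))
  M <- library$n_conformers
  if (is.null(subsample)) subsample <- min(M, 1000L)
  if (subsample > M) stop("subsample exceeds library size")
  idx <- if (subsample < M) {
    with_seed(seed, sample.int(M, subsample))
  } else {
    seq_len(M)
  }
  fr <- attachment_frame(assembly$atoms, res_seq,
                         subunit_index = subunit_index)
  E <- site_environment(assembly, environment, criterion,
                        subunit_index, res_seq)
  # crop the environment once per site: conformers cannot reach beyond
  # their maximum local extent plus the threshold
  Gs <- lapply(library$frames[idx], criterion_glycan_coords,
               criterion = criterion)
  reach <- max(vapply(Gs, function(g) {
    if (nrow(g) == 0) 0 else sqrt(max(rowSums(g^2)))
  }, numeric(1))) + criterion$threshold_A
  d2 <- (E[, 1] - fr$origin[1])^2 + (E[, 2] - fr$origin[2])^2 +
    (E[, 3] - fr$origin[3])^2
  E <- E[d2 <= reach^2, , drop = FALSE]
  acc <- 0L
  for (g in Gs) {
    gg <- sweep(g %*% t(fr$R), 2, fr$origin, "+")
    if (steric_accept(gg, E, criterion)$accepted) acc <- acc + 1L
  }
  anchor <- fr$origin + as.vector(fr$R %*% serine_og_offset())
  list(accepted = acc, total = length(idx),
       fraction = acc / length(idx),
       z_A = anchor[3], subunit = subunit_index, res_seq = res_seq)
}

#' Axially binned accommodation profile of a decorated filament
#'
#' Runs [site_acceptance()] for every (subunit, site) instance of the
#' site map, assigns each instance to the axial bin containing its
#' grafting anchor z-coordinate, and pools accepted/total counts per
#' bin.  Empty bins are flagged (NA fractions), never interpolated.
#'
#' @param assembly Filament `assembly_model`, aligned to +z.
#' @param map A [site_map()] resolvable in every subunit.
#' @param libraries A single [conformer_library()] used for all sites,
#'   or a named list keyed by residue number.
#' @param criterion A [steric_criterion()].
#' @param environment Optional channel (model/atom table/matrix).
#' @param bin_width_A Axial bin width, default 5 A.
#' @param subsample,seed Passed to [site_acceptance()]; each site
#'   instance uses a sub-seed derived deterministically from `seed`.
#' @return Object of class `accommodation_profile`: list with `bins`
#'   (data.frame: z_bin_center_A, n_total, n_accepted,
#'   acceptance_fraction, rejection_rate), `per_site` (one row per site
#'   instance), `bin_edges_A`, `threshold_A`, `bin_width_A`, `seed`.
#' @export
accommodation_profile <- function(assembly, map, libraries,
                                  criterion = steric_criterion(),
                                  environment = NULL, bin_width_A = 5,
                                  subsample = NULL, seed = 1L) {
  stopifnot(inherits(assembly, "assembly_model"), inherits(map, "site_map"))
  res_seqs <- site_map_residues(map)
  if (length(res_seqs) == 0) stop("site map is empty")
  lib_for <- function(rs) {
    if (inherits(libraries, "conformer_library")) return(libraries)
    lib <- libraries[[as.character(rs)]]
    if (is.null(lib)) stop(sprintf("no conformer library for site %d", rs))
    lib
  }
  subs <- sort(unique(assembly$atoms$subunit))
  rows <- list()
  k <- 0L
  for (su in subs) {
    for (rs in res_seqs) {
      k <- k + 1L
      sa <- site_acceptance(assembly, su, rs, lib_for(rs), criterion,
                            environment = environment,
                            subsample = subsample,
                            seed = derive_seed(seed, k))
      rows[[k]] <- data.frame(subunit = su, res_seq = rs, z_A = sa$z_A,
                              accepted = sa$accepted, total = sa$total,
                              fraction = sa$fraction)
    }
  }
  per_site <- do.call(rbind, rows)
  lo <- floor(min(per_site$z_A) / bin_width_A) * bin_width_A
  hi <- ceiling(max(per_site$z_A) / bin_width_A) * bin_width_A
  if (hi <= lo) hi <- lo + bin_width_A
  edges <- seq(lo, hi, by = bin_width_A)
  bin <- findInterval(per_site$z_A, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  n_total <- n_acc <- integer(nb)
  for (b in seq_len(nb)) {
    in_b <- bin == b
    n_total[b] <- sum(per_site$total[in_b])
    n_acc[b] <- sum(per_site$accepted[in_b])
  }
  frac <- ifelse(n_total > 0, n_acc / n_total, NA_real_)
  bins <- data.frame(
    z_bin_center_A = (edges[-1] + edges[-length(edges)]) / 2,
    n_total = n_total, n_accepted = n_acc,
    acceptance_fraction = frac,
    rejection_rate = 1 - frac
  )
  structure(list(bins = bins, per_site = per_site, bin_edges_A = edges,
                 threshold_A = criterion$threshold_A,
                 bin_width_A = bin_width_A, seed = seed),
            class = "accommodation_profile")
}

#' @export
print.accommodation_profile <- function(x, ...) {
  pooled <- sum(x$bins$n_accepted) / max(1, sum(x$bins$n_total))
  cat(sprintf(
    "<accommodation_profile> threshold %.2f A, %d bins, pooled acceptance %.3f\n",
    x$threshold_A, nrow(x$bins), pooled))
  invisible(x)
}

#' Channel aperture profile along the axis
#'
#' Per axial bin, the minimum radial distance sqrt(x^2 + y^2) of channel
#' atoms from the +z axis — the local clearance available to anything
#' passing through.  Empty bins are flagged NA.
#'
#' @param channel `assembly_model` (or atom table) aligned to +z.
#' @param bin_width_A Axial bin width, default 5 A.
#' @return Object of class `aperture_profile`: data.frame with columns
#'   `z_bin_center_A`, `aperture_radius_A`.
#' @export
aperture_profile <- function(channel, bin_width_A = 5) {
  atoms <- if (is.data.frame(channel)) channel else channel$atoms
  if (is.null(atoms) || nrow(atoms) == 0) stop("channel has no atoms")
  z <- atoms$z
  r <- sqrt(atoms$x^2 + atoms$y^2)
  lo <- floor(min(z) / bin_width_A) * bin_width_A
  hi <- ceiling(max(z) / bin_width_A) * bin_width_A
  if (hi <= lo) hi <- lo + bin_width_A
  edges <- seq(lo, hi, by = bin_width_A)
  bin <- findInterval(z, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  ap <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    rb <- r[bin == b]
    if (length(rb) > 0) ap[b] <- min(rb)
  }
  structure(
    data.frame(z_bin_center_A = (edges[-1] + edges[-length(edges)]) / 2,
               aperture_radius_A = ap),
    class = c("aperture_profile", "data.frame")
  )
}

#' Write an accommodation profile as TSV
#'
#' Columns: z_bin_center_A, n_total, n_accepted, acceptance_fraction,
#' rejection_rate; preceded by a comment header recording the threshold
#' and seed.  Output is deterministic.
#'
#' @param profile An `accommodation_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# threshold_A=%.2f seed=%d bin_width_A=%g",
                     profile$threshold_A, as.integer(profile$seed),
                     profile$bin_width_A), con, sep = "\n")
  b <- profile$bins
  lines <- c(paste(names(b), collapse = "\t"),
             apply(b, 1, function(r) {
               paste(c(sprintf("%g", as.numeric(r[1:3])),
                       sprintf("%.6g", as.numeric(r[4:5]))), collapse = "\t")
             }))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write an aperture profile as TSV
#'
#' @param profile An `aperture_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aperture_tsv <- function(profile, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c("z_bin_center_A\taperture_radius_A",
             sprintf("%g\t%.6g", profile$z_bin_center_A,
                     profile$aperture_radius_A))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
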