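# Shared fixtures and independent oracles.  Everything is built in code;
# no stored data files.

# A small hand-built subunit with a serine attachment site at `site`.
# Geometry is irregular enough that Kabsch fits are non-degenerate.
make_tiny_subunit <- function(n_res = 6, site = 3) {
  rows <- list()
  for (k in seq_len(n_res)) {
    base <- c(3 * cos(k), 3 * sin(k), 1.6 * k)
    nm <- c("N", "CA", "C")
    xyz <- rbind(base + c(-1.2, 0.5, -0.4),
                 base,
                 base + c(1.1, 0.8, 0.6))
    at_site <- !is.null(site) && k == site
    rn <- if (at_site) "SER" else "ALA"
    if (at_site) {
      nm <- c(nm, "OG")
      xyz <- rbind(xyz, base + c(0.3, 1.8, 1.5))
    }
    rows[[k]] <- atom_table(seq_len(nrow(xyz)), nm, NULL,
                            rep(rn, nrow(xyz)), rep(k, nrow(xyz)),
                            rep("A", nrow(xyz)), xyz,
                            is_glycan = rep(FALSE, nrow(xyz)))
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  subunit_model(at, site_residues = if (is.null(site)) integer(0) else site)
}

# Identity attachment frame at the origin.
identity_frame <- function() {
  structure(list(origin = c(0, 0, 0), e1 = c(1, 0, 0), e2 = c(0, 1, 0),
                 e3 = c(0, 0, 1), R = diag(3)),
            class = "attachment_frame")
}

# All-pairs brute-force steric decision: explicit loops, no pruning.
brute_force_accept <- function(G, E, threshold) {
  if (nrow(G) == 0 || nrow(E) == 0) {
    return(list(accepted = TRUE, min_distance_A = Inf))
  }
  best <- Inf
  for (i in seq_len(nrow(G))) {
    for (j in seq_len(nrow(E))) {
      d <- sqrt(sum((G[i, ] - E[j, ])^2))
      if (d < best) best <- d
    }
  }
  list(accepted = best >= threshold, min_distance_A = best)
}

# Random proper rotation matrix (uniform axis, uniform angle).
random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_about_axis(ax, stats::runif(1, 5, 175))
}

# Monomer centres of a library conformer: mean of the six ring atoms
# (the hexagon is centred on the monomer centre; the O1 link atom is
# excluded).
monomer_centers <- function(frame_atoms) {
  ring <- frame_atoms[frame_atoms$name != "O1", , drop = FALSE]
  t(vapply(split(seq_len(nrow(ring)), ring$res_seq), function(idx) {
    colMeans(coords(ring[idx, , drop = FALSE]))
  }, numeric(3)))
}

# Pairwise-distance matrix of a coordinate matrix.
pdist <- function(m) as.matrix(stats::dist(m))
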