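# Seeded synthetic generators: pilin-like subunits, self-avoiding glycan
# conformer libraries, and constricted channel models.
#
# Every generator is a pure function of its configuration (seed
# included): the same config yields identical output on every run.

#' Generator configuration
#'
#' Bundles the geometric and sampling parameters for the synthetic
#' subunit, conformer-library and channel generators.  Presets mirror
#' the two filament forms: `"wide"` (125-residue subunit, sites
#' S59/S66/S71) and `"narrow"` (111 residues, site S73); subunit width
#' defaults to 30 A, the approximate width of a pilin subunit.
#'
#' @param seed Integer seed.
#' @param preset `"wide"` or `"narrow"`; fills `subunit_residues` and
#'   `site_residues` unless given explicitly.
#' @param subunit_residues Number of residues in the synthetic subunit.
#' @param subunit_width_A Target bounding-sphere diameter, default 30.
#' @param site_residues Attachment serine residue numbers.
#' @param channel_radius_A Channel wall radius, default 40.
#' @param constriction_depth_A Depth of the Gaussian constriction,
#'   default 15 (must stay below the radius).
#' @param constriction_z_A Axial centre of the constriction; default is
#'   the channel midpoint.
#' @param constriction_sigma_A Gaussian width, default 10.
#' @param channel_length_A Channel length, default 100.
#' @param ring_spacing_A Axial spacing of wall-atom rings, default 2.
#' @param arc_spacing_A Circumferential spacing of wall atoms, default 2.
#' @param conformer_count Library size M, default 500.
#' @param monomers_per_conformer Chain length, default 4.
#' @param step_length_A Monomer centre spacing, default 5.
#' @param min_self_distance_A Self-avoidance distance between
#'   non-adjacent monomer centres, default 4.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             preset = c("wide", "narrow"),
                             subunit_residues = NULL,
                             subunit_width_A = 30,
                             site_residues = NULL,
                             channel_radius_A = 40,
                             constriction_depth_A = 15,
                             constriction_z_A = NULL,
                             constriction_sigma_A = 10,
                             channel_length_A = 100,
                             ring_spacing_A = 2,
                             arc_spacing_A = 2,
                             conformer_count = 500L,
                             monomers_per_conformer = 4L,
                             step_length_A = 5,
                             min_self_distance_A = 4) {
  preset <- match.arg(preset)
  if (is.null(subunit_residues)) {
    subunit_residues <- if (preset == "wide") 125L else 111L
  }
  if (is.null(site_residues)) {
    site_residues <- if (preset == "wide") c(59L, 66L, 71L) else 73L
  }
  if (is.null(constriction_z_A)) constriction_z_A <- channel_length_A / 2
  lengths <- c(subunit_width_A, channel_radius_A, constriction_sigma_A,
               channel_length_A, ring_spacing_A, arc_spacing_A,
               step_length_A, min_self_distance_A)
  if (any(lengths <= 0)) stop("all lengths must be positive")
  if (constriction_depth_A < 0) stop("constriction depth must be >= 0")
  if (any(site_residues >= subunit_residues)) {
    stop("site residues must be below the subunit residue count")
  }
  if (any(site_residues < 1)) stop("site residues must be >= 1")
  structure(list(
    seed = seed, preset = preset,
    subunit_residues = as.integer(subunit_residues),
    subunit_width_A = subunit_width_A,
    site_residues = as.integer(site_residues),
    channel_radius_A = channel_radius_A,
    constriction_depth_A = constriction_depth_A,
    constriction_z_A = constriction_z_A,
    constriction_sigma_A = constriction_sigma_A,
    channel_length_A = channel_length_A,
    ring_spacing_A = ring_spacing_A,
    arc_spacing_A = arc_spacing_A,
    conformer_count = as.integer(conformer_count),
    monomers_per_conformer = as.integer(monomers_per_conformer),
    step_length_A = step_length_A,
    min_self_distance_A = min_self_distance_A
  ), class = "generator_config")
}

#' Generate a synthetic pilin-like subunit
#'
#' Backbone-only model (N, CA, C per residue, plus OG at site serines):
#' an idealized alpha-helical N-terminal segment (the axis-proximal
#' helix of a pilin) topped by a globular head traced on concentric
#' shells, offset from the filament axis so helical packing is
#' realistic.  Site residues are serines with a surface-exposed OG
#' pointing away from the subunit centre.  Small seeded jitter (0.3 A)
#' makes distinct seeds distinct rigid bodies; output is deterministic
#' per seed.
#'
#' @param config A [generator_config()].
#' @return A [subunit_model()] obeying the +z filament convention.
#' @export
make_synthetic_subunit <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$subunit_residues
  if (any(config$site_residues > n)) stop("site residue out of range")
  with_seed(config$seed, {
    h <- min(10L, max(3L, n %/% 6L))
    cx <- 8
    ca <- matrix(0, n, 3)
    for (k in seq_len(h)) {
      a <- k * 100 * pi / 180
      ca[k, ] <- c(cx + 2.3 * cos(a), 2.3 * sin(a), 1.5 * k)
    }
    # globular head: golden-angle ball packing above the helix
    m <- n - h
    rh <- max(4, config$subunit_width_A / 2 - 8)
    center <- c(cx, 0, 1.5 * h + rh)
    golden <- pi * (3 - sqrt(5))
    for (j in seq_len(m)) {
      rad <- rh * (j / m)^(1 / 3)
      cz <- 1 - 2 * j / (m + 1)
      sz <- sqrt(max(0, 1 - cz^2))
      a <- j * golden
      ca[h + j, ] <- center + rad * c(sz * cos(a), sz * sin(a), cz)
    }
    ca <- ca + matrix(stats::rnorm(3 * n, sd = 0.3), n, 3)

    # rescale the trace about its centroid so the bounding-sphere
    # diameter matches the configured subunit width
    cen <- colMeans(ca)
    diam <- max(stats::dist(ca))
    ca <- sweep(sweep(ca, 2, cen) * (config$subunit_width_A / diam), 2,
                cen, "+")

    sub_center <- colMeans(ca)
    res_name <- rep("ALA", n)
    res_name[config$site_residues] <- "SER"
    rows <- vector("list", n)
    for (k in seq_len(n)) {
      prev <- if (k > 1) ca[k - 1, ] else ca[k, ] - c(0, 0, 1)
      nxt <- if (k < n) ca[k + 1, ] else ca[k, ] + c(0, 0, 1)
      t_dir <- unit3(nxt - prev)
      vw <- perp_basis(t_dir)
      p <- vw[, 1]
      npos <- ca[k, ] + 1.45 * unit3(-t_dir + p)
      cpos <- ca[k, ] + 1.52 * unit3(t_dir + 0.5 * p)
      names_k <- c("N", "CA", "C")
      xyz_k <- rbind(npos, ca[k, ], cpos)
      if (res_name[k] == "SER") {
        out <- unit3(ca[k, ] - sub_center)
        xyz_k <- rbind(xyz_k, ca[k, ] + 2.4 * out)
        names_k <- c(names_k, "OG")
      }
      rows[[k]] <- atom_table(
        seq_len(nrow(xyz_k)), names_k,
        c("N", "C", "C", "O")[seq_len(nrow(xyz_k))],
        rep(res_name[k], nrow(xyz_k)), rep(k, nrow(xyz_k)),
        rep("A", nrow(xyz_k)), xyz_k, is_glycan = rep(FALSE, nrow(xyz_k)))
    }
    at <- do.call(rbind, rows)
    at$serial <- seq_len(nrow(at))
    subunit_model(at, site_residues = config$site_residues)
  })
}

#' @keywords internal
rand_unit <- function() {
  cz <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  sz <- sqrt(max(0, 1 - cz^2))
  c(sz * cos(phi), sz * sin(phi), cz)
}

#' Sample a self-avoiding glycan conformer library
#'
#' Each conformer is a random chain of monomer hexagon templates: the
#' first monomer centre sits 2.5 A beyond the serine O-gamma offset
#' along a random direction, and each successive centre is one
#' `step_length_A` away in a fresh uniformly random direction, accepted
#' only if it keeps at least `min_self_distance_A` from all non-adjacent
#' previous centres (up to 100 retries per step, then the chain
#' restarts; after 200 failed restarts the sampler errors, suggesting
#' looser parameters).  Sampling is fully determined by the seed.
#'
#' @param config A [generator_config()]; uses `conformer_count`,
#'   `monomers_per_conformer`, `step_length_A`, `min_self_distance_A`
#'   and `seed`.
#' @param topology Optional [glycan_topology()] fixing chain length and
#'   monomer codes (overrides `monomers_per_conformer`).
#' @return A [conformer_library()] in local attachment-frame
#'   coordinates.
#' @export
sample_conformer_library <- function(config, topology = NULL) {
  stopifnot(inherits(config, "generator_config"))
  K <- if (!is.null(topology)) length(topology$monomers) else
    config$monomers_per_conformer
  if (K < 1) stop("need at least one monomer per conformer")
  M <- config$conformer_count
  if (M < 1) stop("need at least one conformer")
  codes <- if (!is.null(topology)) rev(topology$monomers) else
    rep("N", K)
  res_names <- glycan_res_names()[codes]
  og <- serine_og_offset()
  step <- config$step_length_A
  dmin2 <- config$min_self_distance_A^2

  with_seed(config$seed, {
    frames <- vector("list", M)
    for (mi in seq_len(M)) {
      centers <- dirs <- NULL
      for (restart in seq_len(200)) {
        ok <- TRUE
        centers <- matrix(0, K, 3)
        dirs <- matrix(0, K, 3)
        d1 <- rand_unit()
        dirs[1, ] <- d1
        centers[1, ] <- og + 2.5 * d1
        if (K > 1) {
          for (k in 2:K) {
            placed <- FALSE
            for (try in seq_len(100)) {
              u <- rand_unit()
              cand <- centers[k - 1, ] + step * u
              clash <- FALSE
              if (k > 2) {
                for (j in 1:(k - 2)) {
                  dd <- cand - centers[j, ]
                  if (sum(dd * dd) < dmin2) { clash <- TRUE; break }
                }
              }
              if (!clash) {
                centers[k, ] <- cand
                dirs[k, ] <- u
                placed <- TRUE
                break
              }
            }
            if (!placed) { ok <- FALSE; break }
          }
        }
        if (ok) break
        if (restart == 200) {
          stop("self-avoiding sampling failed; loosen min_self_distance_A or step_length_A")
        }
      }
      pieces <- lapply(seq_len(K), function(k) {
        monomer_template_atoms(centers[k, ], dirs[k, ], res_names[[k]], k)
      })
      at <- do.call(rbind, pieces)
      at$serial <- seq_len(nrow(at))
      frames[[mi]] <- at
    }
    conformer_library(frames, topology = topology, seed = config$seed)
  })
}

#' Generate a synthetic channel with one Gaussian constriction
#'
#' A pseudo-atom cylinder on +z: rings of wall atoms at `ring_spacing_A`
#' axial intervals, `arc_spacing_A` apart along each ring, with local
#' radius `R(z) = channel_radius_A - constriction_depth_A *
#' exp(-(z - z0)^2 / (2 sigma^2))`.  Wall atoms are named CA (non-glycan)
#' so the default steric criterion sees them.  Purely deterministic —
#' no random numbers are drawn.
#'
#' @param config A [generator_config()].
#' @return An `assembly_model` of kind `"channel"`.
#' @export
make_channel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$constriction_depth_A >= config$channel_radius_A) {
    stop("constriction depth >= channel radius would close the channel; request explicitly via a custom generator")
  }
  zs <- seq(0, config$channel_length_A, by = config$ring_spacing_A)
  rows <- vector("list", length(zs))
  res <- 0L
  for (i in seq_along(zs)) {
    z <- zs[i]
    R <- config$channel_radius_A - config$constriction_depth_A *
      exp(-(z - config$constriction_z_A)^2 /
            (2 * config$constriction_sigma_A^2))
    na <- max(3L, ceiling(2 * pi * R / config$arc_spacing_A))
    a <- 2 * pi * (seq_len(na) - 1) / na
    xyz <- cbind(R * cos(a), R * sin(a), rep(z, na))
    rows[[i]] <- atom_table(seq_len(na), rep("CA", na), rep("C", na),
                            rep("GLY", na), res + seq_len(na),
                            rep("Q", na), xyz,
                            is_glycan = rep(FALSE, na))
    res <- res + na
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  at$subunit <- 1L
  assembly_model(at, kind = "channel")
}
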