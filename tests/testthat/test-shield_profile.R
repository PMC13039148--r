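test_that("steric decisions follow the threshold rule", {
  crit <- steric_criterion(3.25)
  # empty environment accepts with infinite clearance
  r <- steric_accept(matrix(c(0, 0, 0), 1), matrix(numeric(0), 0, 3), crit)
  expect_true(r$accepted)
  expect_equal(r$min_distance_A, Inf)

  # coincident atoms reject
  r <- steric_accept(matrix(c(1, 2, 3), 1), matrix(c(1, 2, 3), 1), crit)
  expect_false(r$accepted)
  expect_equal(r$min_distance_A, 0)

  # distance exactly at the threshold counts as accepted
  r <- steric_accept(matrix(c(0, 0, 0), 1), matrix(c(3.25, 0, 0), 1), crit)
  expect_true(r$accepted)

  # empty glycan selection accepts
  chain <- build_glycan_chain(glycan_topology("N"))
  no_ring <- chain[chain$name != "O5", ]
  r <- steric_accept(no_ring, matrix(c(0, 0, 0), 1), crit)
  expect_true(r$accepted)

  expect_error(steric_criterion(0))
})

test_that("pruned evaluation matches the all-pairs brute-force oracle", {
  set.seed(33)
  for (rep in 1:20) {
    G <- matrix(stats::rnorm(15, sd = 4), 5, 3)
    E <- matrix(stats::runif(450, -12, 12), 150, 3)
    thr <- stats::runif(1, 1, 6)
    crit <- steric_criterion(thr)
    fast <- steric_accept(G, E, crit)
    ref <- brute_force_accept(G, E, thr)
    expect_identical(fast$accepted, ref$accepted)
    expect_equal(fast$min_distance_A, ref$min_distance_A, tolerance = 1e-12)
  }
})

test_that("site acceptance is seeded, reproducible, and limits correctly", {
  su <- make_synthetic_subunit(generator_config(seed = 2))
  fil <- apply_helical_symmetry(su, helical_params(92.4, 9.2), 3)
  lib <- sample_conformer_library(
    generator_config(seed = 5, conformer_count = 40, monomers_per_conformer = 2))

  a1 <- site_acceptance(fil, 2, 66, lib, steric_criterion(3.25),
                        subsample = 20, seed = 3)
  a2 <- site_acceptance(fil, 2, 66, lib, steric_criterion(3.25),
                        subsample = 20, seed = 3)
  expect_identical(a1[c("accepted", "total")], a2[c("accepted", "total")])
  expect_equal(a1$total, 20)
  expect_equal(a1$fraction, a1$accepted / a1$total)
  expect_error(site_acceptance(fil, 2, 66, lib, subsample = 100), "exceeds")

  # vanishing threshold with non-coincident atoms accepts everything
  tiny <- site_acceptance(fil, 2, 66, lib, steric_criterion(1e-9))
  expect_equal(tiny$fraction, 1)
})

test_that("acceptance is monotone in threshold and environment size", {
  su <- make_synthetic_subunit(generator_config(seed = 2))
  fil <- apply_helical_symmetry(su, helical_params(92.4, 9.2), 3)
  lib <- sample_conformer_library(
    generator_config(seed = 5, conformer_count = 60))

  fr_low <- site_acceptance(fil, 2, 66, lib, steric_criterion(3.25),
                            seed = 1)$fraction
  fr_high <- site_acceptance(fil, 2, 66, lib, steric_criterion(3.75),
                             seed = 1)$fraction
  expect_lte(fr_high, fr_low)

  # adding environment atoms can never increase acceptance
  ch <- make_channel(generator_config(seed = 1, channel_radius_A = 25,
                                      constriction_depth_A = 0))
  with_ch <- site_acceptance(fil, 2, 66, lib, steric_criterion(3.25),
                             environment = ch, seed = 1)$fraction
  expect_lte(with_ch, fr_low)
})

test_that("profiles ignore unreachable walls and flag empty bins", {
  su <- make_synthetic_subunit(generator_config(seed = 2))
  fil <- apply_helical_symmetry(su, helical_params(92.4, 9.2), 4)
  lib <- sample_conformer_library(
    generator_config(seed = 5, conformer_count = 30))
  crit <- steric_criterion(3.25)
  libs <- list(`59` = lib, `66` = lib, `71` = lib)

  bare <- accommodation_profile(fil, site_map("wide"), libs, crit,
                                subsample = 15, seed = 2)
  far <- make_channel(generator_config(seed = 1, channel_radius_A = 500,
                                       constriction_depth_A = 0,
                                       ring_spacing_A = 10,
                                       arc_spacing_A = 20))
  walled <- accommodation_profile(fil, site_map("wide"), libs, crit,
                                  environment = far, subsample = 15,
                                  seed = 2)
  expect_identical(bare$bins, walled$bins)
  expect_true(all(is.na(bare$bins$acceptance_fraction[bare$bins$n_total == 0])))
  expect_equal(nrow(bare$per_site), 4 * 3)

  # an environment grid denser than the threshold blocks everything
  rng <- range(c(bare$per_site$z_A, coords(fil$atoms)[, 3]))
  gx <- seq(-40, 40, by = 2); gz <- seq(rng[1] - 25, rng[2] + 25, by = 2)
  grid <- as.matrix(expand.grid(x = gx, y = gx, z = gz))
  blocked <- accommodation_profile(fil, site_map("wide"), libs, crit,
                                   environment = grid, subsample = 5,
                                   seed = 2)
  pop <- blocked$bins$n_total > 0
  expect_true(all(blocked$bins$acceptance_fraction[pop] == 0))
})

test_that("aperture profiles recover cylinder geometry", {
  cyl <- make_channel(generator_config(seed = 1, channel_radius_A = 30,
                                       constriction_depth_A = 0))
  ap <- aperture_profile(cyl, 5)
  expect_true(all(abs(ap$aperture_radius_A - 30) < 1e-9))

  con <- make_channel(generator_config(seed = 1, channel_radius_A = 30,
                                       constriction_depth_A = 12,
                                       constriction_z_A = 50,
                                       constriction_sigma_A = 6))
  ap2 <- aperture_profile(con, 5)
  imin <- which.min(ap2$aperture_radius_A)
  expect_equal(ap2$z_bin_center_A[imin], 52.5)
  expect_equal(min(ap2$aperture_radius_A), 30 - 12, tolerance = 0.05)

  # single ring populates exactly one bin
  ring <- make_channel(generator_config(seed = 1, channel_length_A = 1,
                                        ring_spacing_A = 2,
                                        constriction_depth_A = 0))
  ap3 <- aperture_profile(ring, 5)
  expect_equal(sum(!is.na(ap3$aperture_radius_A)), 1)

  expect_error(aperture_profile(cyl$atoms[0, ]), "no atoms")
})

test_that("profile TSV output is deterministic and self-describing", {
  su <- make_synthetic_subunit(generator_config(seed = 2))
  fil <- apply_helical_symmetry(su, helical_params(84, 11.3), 3)
  lib <- sample_conformer_library(
    generator_config(seed = 5, conformer_count = 20))
  prof <- accommodation_profile(fil, site_map("narrow"), lib,
                                steric_criterion(3.75), subsample = 10,
                                seed = 4)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_profile_tsv(prof, p1)
  write_profile_tsv(prof, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_match(readLines(p1)[1], "threshold_A=3.75 seed=4")
  back <- utils::read.delim(p1, comment.char = "#")
  expect_equal(back$n_total, prof$bins$n_total)
  expect_equal(back$n_accepted, prof$bins$n_accepted)

  ap <- aperture_profile(make_channel(generator_config(seed = 1)), 5)
  pa <- withr::local_tempfile()
  write_aperture_tsv(ap, pa)
  back2 <- utils::read.delim(pa)
  expect_equal(back2$z_bin_center_A, ap$z_bin_center_A)
})
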