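test_that("helical symmetry places subunits on the screw lattice", {
  su <- make_tiny_subunit(5, site = 3)
  # n = 1 is the identity
  one <- apply_helical_symmetry(su, helical_params(92.4, 9.2), 1)
  expect_equal(coords(one$atoms), coords(su), tolerance = 1e-12)

  # single atom, quarter turn: (5,0,0) -> (0,5,2)
  pt <- subunit_model(atom_table(1, "CA", "C", "ALA", 1, "A",
                                 matrix(c(5, 0, 0), 1)))
  fil <- apply_helical_symmetry(pt, helical_params(90, 2), 2)
  expect_equal(coords(fil$atoms)[2, ], c(x = 0, y = 5, z = 2),
               tolerance = 1e-12)

  # 125-residue subunit, 45 copies: 5625 residues, wrapped chain ids
  wide <- make_synthetic_subunit(generator_config(seed = 1))
  f45 <- apply_helical_symmetry(wide, helical_params(92.4, 9.2), 45)
  expect_equal(count_residues(f45), 5625)
  expect_equal(unique(f45$atoms$chain_id[f45$atoms$subunit == 27]), "A")

  expect_error(apply_helical_symmetry(su, helical_params(92.4, 9.2), 0))
  expect_error(helical_params(200, 9.2))
  expect_error(helical_params(92.4, -1))
})

test_that("screw-transform fitting inverts the helical operator", {
  su <- make_tiny_subunit(6, site = 3)
  fil <- apply_helical_symmetry(su, helical_params(84.0, 11.3), 3)
  a <- fil$atoms[fil$atoms$subunit == 1, ]
  b <- fil$atoms[fil$atoms$subunit == 2, ]
  s <- fit_screw_transform(a, b)
  expect_equal(s$rotation_angle_deg, 84.0, tolerance = 1e-9)
  expect_equal(abs(s$translation_along_axis_A), 11.3, tolerance = 1e-9)
  expect_equal(abs(s$axis_direction[3]), 1, tolerance = 1e-9)
  expect_lt(s$rmsd, 1e-6)

  # pure translation decomposes to zero rotation
  b2 <- transform_model(a, t = c(0, 0, 5))
  s2 <- fit_screw_transform(a, b2)
  expect_equal(s2$rotation_angle_deg, 0, tolerance = 1e-9)
  expect_equal(s2$translation_along_axis_A, 5, tolerance = 1e-9)
})

test_that("fitted rotation angle matches the closed-form trace oracle", {
  set.seed(71)
  for (rep in 1:10) {
    R <- random_rotation()
    cloud <- matrix(stats::rnorm(150, sd = 6), 50, 3)
    t_axis <- stats::rnorm(3)
    moved <- sweep(cloud %*% t(R), 2, t_axis, "+")
    s <- fit_screw_transform(
      atom_table(1:50, rep("CA", 50), NULL, rep("ALA", 50), 1:50,
                 rep("A", 50), cloud),
      atom_table(1:50, rep("CA", 50), NULL, rep("ALA", 50), 1:50,
                 rep("A", 50), moved))
    oracle_angle <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
    expect_equal(s$rotation_angle_deg, oracle_angle, tolerance = 1e-9)
    expect_lt(s$rmsd, 1e-9)
  }
})

test_that("helical parameters are recovered across a random sweep", {
  set.seed(5)
  for (rep in 1:8) {
    twist <- stats::runif(1, 1, 179) * sample(c(-1, 1), 1)
    rise <- stats::runif(1, 1, 20)
    su <- make_tiny_subunit(6, site = 3)
    su <- transform_model(su, R = random_rotation(), t = stats::rnorm(3, sd = 4))
    fil <- apply_helical_symmetry(su, helical_params(twist, rise), 4)
    fit <- fit_helical_parameters(fil)
    expect_equal(fit$twist_deg, twist, tolerance = 1e-6)
    expect_equal(fit$rise_A, rise, tolerance = 1e-6)
    expect_false(fit$degenerate)
  }
})

test_that("degenerate and inconsistent filaments are flagged", {
  su <- make_tiny_subunit(5, site = 3)
  ident <- apply_helical_symmetry(su, helical_params(92.4, 9.2), 1)
  two <- ident$atoms
  two2 <- two; two2$subunit <- 2L
  flat <- assembly_model(rbind(two, two2), kind = "filament")
  fit <- fit_helical_parameters(flat)
  expect_true(fit$degenerate)
  expect_equal(fit$twist_deg, 0, tolerance = 1e-9)

  fil <- apply_helical_symmetry(su, helical_params(92.4, 9.2), 4)
  noisy <- fil
  idx <- which(noisy$atoms$subunit == 3)
  set.seed(4)
  noisy$atoms$x[idx] <- noisy$atoms$x[idx] + stats::rnorm(length(idx), sd = 5)
  noisy$atoms$y[idx] <- noisy$atoms$y[idx] + stats::rnorm(length(idx), sd = 5)
  expect_error(fit_helical_parameters(noisy), "inconsistent")
})

test_that("screw composition, isometry and Cn closure hold", {
  su <- make_tiny_subunit(6, site = 3)
  params <- helical_params(92.4, 9.2)
  fil <- apply_helical_symmetry(su, params, 5)
  a0 <- coords(fil$atoms[fil$atoms$subunit == 1, ])
  s <- fit_screw_transform(fil$atoms[fil$atoms$subunit == 1, ],
                           fil$atoms[fil$atoms$subunit == 2, ])
  R1 <- rotation_about_axis(s$axis_direction, s$rotation_angle_deg)
  step <- function(m) {
    p <- s$axis_point
    sweep(sweep(m, 2, p) %*% t(R1), 2,
          p + s$translation_along_axis_A * s$axis_direction, "+")
  }
  m <- a0
  for (k in 2:5) {
    m <- step(m)
    expect_equal(m, coords(fil$atoms[fil$atoms$subunit == k, ]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # isometry: within-subunit distances preserved
  expect_equal(pdist(coords(fil$atoms[fil$atoms$subunit == 4, ])),
               pdist(coords(su$atoms)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # Cn closure: applying the step rotation `order` times is the identity
  for (ord in c(6, 13)) {
    cn <- cn_params(ord)
    R <- diag(3)
    for (i in seq_len(ord)) R <- rot_z(cn$step_deg) %*% R
    expect_equal(R, diag(3), tolerance = 1e-9)
  }
})

test_that("Cn rings are invariant under their step rotation", {
  su <- transform_model(make_tiny_subunit(5, site = 3), t = c(20, 0, 0))
  expect_equal(cn_step_display(cn_params(13)), "27.7")
  expect_error(cn_params(0))

  ring1 <- build_cn_ring(su, 1)
  expect_equal(coords(ring1$atoms), coords(su$atoms), tolerance = 1e-12)

  for (ord in c(6, 13)) {
    ring <- build_cn_ring(su, ord)
    rot <- coords(ring$atoms) %*% t(rot_z(360 / ord))
    orig <- coords(ring$atoms)
    # sort-and-compare oracle on the coordinate multiset
    key <- function(m) m[order(round(m[, 1], 6), round(m[, 2], 6),
                               round(m[, 3], 6)), ]
    expect_equal(key(rot), key(orig), tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("align_to_axis maps arbitrary axes onto +z isometrically", {
  su <- make_tiny_subunit(6, site = 3)
  same <- align_to_axis(su, c(0, 0, 0), c(0, 0, 1))
  expect_equal(coords(same$atoms), coords(su$atoms), tolerance = 1e-12)

  alongx <- align_to_axis(su, c(0, 0, 0), c(1, 0, 0))
  expect_equal(pdist(coords(alongx$atoms)), pdist(coords(su$atoms)),
               tolerance = 1e-9, ignore_attr = TRUE)

  set.seed(9)
  for (rep in 1:5) {
    a <- stats::rnorm(3, sd = 5); b <- a + stats::rnorm(3)
    probe <- atom_table(1:2, c("CA", "CA"), NULL, c("ALA", "ALA"), 1:2,
                        c("A", "A"), rbind(a, b))
    al <- align_to_axis(probe, a, b)
    m <- coords(al)
    expect_equal(m[1, ], c(x = 0, y = 0, z = 0), tolerance = 1e-9)
    expect_equal(m[2, 1:2], c(x = 0, y = 0), tolerance = 1e-9)
    expect_gt(m[2, 3], 0)
  }
  expect_error(align_to_axis(su, c(1, 1, 1), c(1, 1, 1)), "coincident")
})
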