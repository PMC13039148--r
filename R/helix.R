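# Screw (helical) symmetry and Cn point-group operations.
#
# Convention: the filament/channel axis is +z through the origin and
# positive twist is a right-handed rotation about +z.  Twist is reported
# in (-180, 180].

#' Rotation matrix about the z axis
#' @param angle_deg Rotation angle in degrees (right-handed about +z).
#' @return 3x3 rotation matrix.
#' @export
rot_z <- function(angle_deg) {
  th <- angle_deg * pi / 180
  matrix(c(cos(th), sin(th), 0,
           -sin(th), cos(th), 0,
           0, 0, 1), nrow = 3)
}

#' Rotation matrix about an arbitrary axis (Rodrigues formula)
#' @param axis 3-vector; normalized internally.
#' @param angle_deg Rotation angle in degrees (right-handed about `axis`).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), nrow = 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to a model
#'
#' New coordinates are `R x + t` per atom.  All model classes are
#' supported; the class and all non-coordinate fields are preserved.
#'
#' @param model `subunit_model`, `assembly_model` or atom table.
#' @param R 3x3 rotation matrix (default identity).
#' @param t Translation 3-vector (default zero).
#' @return Transformed model of the same class.
#' @export
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  apply_rigid <- function(atoms) {
    m <- coords(atoms) %*% t(R)
    set_coords(atoms, sweep(m, 2, t, "+"))
  }
  if (is.data.frame(model)) return(apply_rigid(model))
  model$atoms <- apply_rigid(model$atoms)
  model
}

#' Build a helical filament from a single subunit
#'
#' Subunit copy k (k = 0..n-1) has coordinates
#' `Rz(k * twist) x + (0, 0, k * rise)`.  The subunit must already be
#' expressed in the +z axis convention (see [align_to_axis()]).  Chain
#' identifiers run A, B, ... and wrap after Z; atom order within each
#' subunit is preserved.
#'
#' @param subunit A `subunit_model`, pre-aligned to the +z convention.
#' @param params [helical_params()]: twist (deg) and rise (Angstrom).
#' @param n Number of subunits (>= 1).
#' @return An `assembly_model` of kind `"filament"`.
#' @export
apply_helical_symmetry <- function(subunit, params, n) {
  if (!inherits(params, "helical_params")) {
    params <- helical_params(params[[1]], params[[2]])
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("number of subunits must be >= 1")
  x0 <- coords(subunit$atoms)
  pieces <- vector("list", n)
  for (k in seq_len(n) - 1L) {
    at <- subunit$atoms
    m <- x0 %*% t(rot_z(k * params$twist_deg))
    m[, 3] <- m[, 3] + k * params$rise_A
    at <- set_coords(at, m)
    at$chain_id <- LETTERS[(k %% 26L) + 1L]
    at$subunit <- k + 1L
    pieces[[k + 1L]] <- at
  }
  assembly_model(do.call(rbind, pieces), kind = "filament",
                 site_residues = subunit$site_residues)
}

#' Build a Cn ring from a pre-placed subunit
#'
#' Places `order` copies of the subunit at rotations of k*(360/order)
#' degrees about +z.  The subunit must already sit at its ring radius;
#' this operator only rotates.
#'
#' @param subunit A `subunit_model` at its ring position.
#' @param order Cn order (integer >= 1), e.g. 13 for a secretin, 6 for
#'   the motor-ATPase platform.
#' @return An `assembly_model` of kind `"ring"`.
#' @export
build_cn_ring <- function(subunit, order) {
  cn <- cn_params(order)
  pieces <- vector("list", cn$order)
  x0 <- coords(subunit$atoms)
  for (k in seq_len(cn$order) - 1L) {
    at <- subunit$atoms
    at <- set_coords(at, x0 %*% t(rot_z(k * cn$step_deg)))
    at$chain_id <- LETTERS[(k %% 26L) + 1L]
    at$subunit <- k + 1L
    pieces[[k + 1L]] <- at
  }
  assembly_model(do.call(rbind, pieces), kind = "ring",
                 site_residues = subunit$site_residues)
}

#' @keywords internal
kabsch <- function(A, B) {
  # least-squares proper rotation R and translation t with B ~ A R^T + t
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  s <- svd(H)
  # canonical column signs: largest-magnitude entry of each u column >= 0
  for (j in 1:3) {
    i <- which.max(abs(s$u[, j]))
    if (s$u[i, j] < 0) {
      s$u[, j] <- -s$u[, j]
      s$v[, j] <- -s$v[, j]
    }
  }
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) stop("degenerate geometry: atoms are collinear or coincident")
  reflection <- d < 0
  if (reflection) {
    warning("reflection-optimal superposition; forcing proper rotation")
    s$v[, 3] <- -s$v[, 3]
  }
  R <- s$v %*% t(s$u)
  t <- cb - as.vector(R %*% ca)
  fit <- sweep(A %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fit - B)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' @keywords internal
screw_from_rigid <- function(R, t, tol = 1e-9) {
  cth <- (sum(diag(R)) - 1) / 2
  cth <- max(-1, min(1, cth))
  theta <- acos(cth)
  if (theta < tol) {
    nt <- sqrt(sum(t^2))
    axis <- if (nt > tol) t / nt else c(0, 0, 1)
    return(list(angle_deg = 0, axis = axis, point = c(0, 0, 0),
                translation = sum(t * axis)))
  }
  if (abs(theta - pi) < 1e-6) {
    B <- (R + diag(3)) / 2
    j <- which.max(diag(B))
    axis <- B[, j] / sqrt(B[j, j])
    nz <- which(abs(axis) > tol)[1]
    if (axis[nz] < 0) axis <- -axis
  } else {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(theta))
  }
  d <- sum(t * axis)
  t_perp <- t - d * axis
  # axis point: least-squares solution of (I - R) p = t_perp, p orthogonal
  # to the axis (the system is rank 2)
  M <- rbind(diag(3) - R, axis)
  p <- qr.solve(M, c(t_perp, 0))
  list(angle_deg = theta * 180 / pi, axis = axis, point = as.numeric(p),
       translation = d)
}

#' Fit the screw transform between two corresponding subunits
#'
#' Superposes `subunit_a` onto `subunit_b` by least-squares rigid fit
#' (Kabsch with proper-rotation enforcement) and decomposes the rigid map
#' into a rotation about a fitted axis plus a translation along it.
#' Atoms must correspond by order.
#'
#' @param subunit_a,subunit_b `subunit_model`s (or atom tables) with
#'   identical atom counts; at least 3 non-collinear atoms.
#' @return Object of class `screw_transform` with fields
#'   `rotation_angle_deg` (in \[0, 180\]), `axis_direction` (unit vector),
#'   `axis_point`, `translation_along_axis_A`, `rmsd`.
#' @export
fit_screw_transform <- function(subunit_a, subunit_b) {
  A <- coords(subunit_a); B <- coords(subunit_b)
  if (nrow(A) != nrow(B)) stop("subunits have different atom counts")
  if (nrow(A) < 3) stop("need at least 3 atoms to fit a screw transform")
  k <- kabsch(A, B)
  s <- screw_from_rigid(k$R, k$t)
  structure(
    list(rotation_angle_deg = s$angle_deg,
         axis_direction = s$axis,
         axis_point = s$point,
         translation_along_axis_A = s$translation,
         rmsd = k$rmsd),
    class = "screw_transform"
  )
}

#' @export
print.screw_transform <- function(x, ...) {
  cat(sprintf(
    "<screw_transform> angle %.4f deg, translation %.4f A, axis (%.3f, %.3f, %.3f), rmsd %.2e\n",
    x$rotation_angle_deg, x$translation_along_axis_A,
    x$axis_direction[1], x$axis_direction[2], x$axis_direction[3], x$rmsd))
  invisible(x)
}

#' @keywords internal
canonical_z_screw <- function(s) {
  # express angle/translation with the axis pointing along +z
  ang <- s$rotation_angle_deg
  ax <- s$axis_direction
  d <- s$translation_along_axis_A
  if (ax[3] < 0) {
    ax <- -ax; ang <- -ang; d <- -d
  }
  list(angle = ang, translation = d, axis = ax)
}

#' Recover helical parameters from a filament
#'
#' Fits screw transforms for all consecutive subunit pairs, canonicalizes
#' them to the right-handed +z convention, and averages: circular mean
#' for the twist, arithmetic mean for the rise.  Pairs deviating from the
#' mean by more than the tolerance raise an error naming them.
#'
#' @param filament An `assembly_model` with >= 2 subunits.
#' @param angle_tol_deg,rise_tol_A Maximum allowed deviation of any pair
#'   from the mean (defaults 0.5 deg / 0.5 Angstrom).
#' @return List with `params` ([helical_params()] or NULL when
#'   degenerate), `twist_deg`, `rise_A`, `max_angle_dev_deg`,
#'   `max_rise_dev_A`, `rmsd` (max pair residual), `degenerate`.
#' @export
fit_helical_parameters <- function(filament, angle_tol_deg = 0.5,
                                   rise_tol_A = 0.5) {
  stopifnot(inherits(filament, "assembly_model"))
  subs <- sort(unique(filament$atoms$subunit))
  if (length(subs) < 2) stop("need at least 2 subunits")
  pairs <- length(subs) - 1L
  ang <- num <- rep(NA_real_, pairs)
  rise <- rep(NA_real_, pairs)
  rmsd <- rep(NA_real_, pairs)
  for (i in seq_len(pairs)) {
    a <- filament$atoms[filament$atoms$subunit == subs[i], , drop = FALSE]
    b <- filament$atoms[filament$atoms$subunit == subs[i + 1], , drop = FALSE]
    s <- fit_screw_transform(a, b)
    cz <- canonical_z_screw(s)
    ang[i] <- cz$angle
    rise[i] <- cz$translation
    rmsd[i] <- s$rmsd
  }
  th <- ang * pi / 180
  mean_twist <- atan2(mean(sin(th)), mean(cos(th))) * 180 / pi
  mean_rise <- mean(rise)
  wrap <- function(x) ((x + 180) %% 360) - 180
  adev <- abs(wrap(ang - mean_twist))
  rdev <- abs(rise - mean_rise)
  degenerate <- all(abs(ang) < 1e-6) && all(abs(rise) < 1e-6)
  bad <- which(adev > angle_tol_deg | rdev > rise_tol_A)
  if (length(bad) > 0) {
    stop(sprintf(
      "inconsistent screw transforms for subunit pair(s): %s (max dev %.3g deg / %.3g A)",
      paste(bad, collapse = ", "), max(adev), max(rdev)))
  }
  params <- if (degenerate) NULL else helical_params(mean_twist, abs(mean_rise))
  list(params = params, twist_deg = mean_twist, rise_A = mean_rise,
       max_angle_dev_deg = max(adev), max_rise_dev_A = max(rdev),
       rmsd = max(rmsd), degenerate = degenerate)
}

#' Rigidly align a model so a given axis maps onto +z through the origin
#'
#' The point `axis_point_a` maps to the origin and the direction
#' `axis_point_b - axis_point_a` to +z.  Distances are preserved.
#'
#' @param model Any model or atom table.
#' @param axis_point_a,axis_point_b Two distinct points on the desired
#'   axis.
#' @return Transformed model of the same class.
#' @export
align_to_axis <- function(model, axis_point_a, axis_point_b) {
  u <- axis_point_b - axis_point_a
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stop("axis points are coincident")
  u <- u / nu
  ez <- c(0, 0, 1)
  cr <- c(u[2] * ez[3] - u[3] * ez[2],
          u[3] * ez[1] - u[1] * ez[3],
          u[1] * ez[2] - u[2] * ez[1])
  sn <- sqrt(sum(cr^2))
  cs <- sum(u * ez)
  R <- if (sn < 1e-12) {
    if (cs > 0) diag(3) else rotation_about_axis(c(1, 0, 0), 180)
  } else {
    rotation_about_axis(cr, atan2(sn, cs) * 180 / pi)
  }
  transform_model(model, R = R, t = -as.vector(R %*% axis_point_a))
}
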