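set.seed(1)
cloud <- matrix(rnorm(60, sd = 5), 20, 3)

test_that("superpose on identical sets gives identity and rmsd 0", {
  fit <- superpose(cloud, cloud)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
})

test_that("superpose recovers a planted 12-degree rotation to 1e-6", {
  R <- oracle_rotation(c(1, 2, -0.5), 12)
  moved <- cloud %*% t(R) + matrix(c(3, -1, 7), 20, 3, byrow = TRUE)
  fit <- superpose(moved, cloud)
  expect_lt(max(abs(fit$rotation %*% R - diag(3))), 1e-6)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(apply_transform(moved, fit), cloud, tolerance = 1e-9)
})

test_that("superpose returns a proper rotation on chirally flipped input", {
  flipped <- cloud %*% diag(c(-1, 1, 1))
  fit <- superpose(flipped, cloud)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.1)
})

test_that("superpose rejects degenerate input", {
  expect_error(superpose(cloud[1:2, ], cloud[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(cloud[1:5, ], cloud), "equal-sized")
})

test_that("rmsd is invariant to rigid pre-transforms of mobile (property)", {
  target <- cloud + matrix(rnorm(60, sd = 0.5), 20, 3)
  base <- superpose(cloud, target)$rmsd
  set.seed(7)
  for (i in 1:10) {
    R <- oracle_rotation(rnorm(3), runif(1, 0, 180))
    t0 <- rnorm(3, sd = 20)
    pre <- cloud %*% t(R) + matrix(t0, 20, 3, byrow = TRUE)
    expect_equal(superpose(pre, target)$rmsd, base, tolerance = 1e-9)
  }
})

# --- helix angle -----------------------------------------------------------

ref_out <- make_ensemble(ensemble_spec(
  n_frames = 1, fractions = c(R_like = 1, T_like = 0, intermediate = 0),
  coord_noise_sd = 0, seed = 41))
reference <- ref_out$reference

test_that("X-alignment maps an arbitrary helix onto +X", {
  # rotate the whole reference rigidly so the helix points along +Z
  rot <- ref_out$reference
  R <- oracle_rotation(c(0, 1, 0), -90)  # +X -> +Z
  for (f in 1) rot$coords[, , f] <- rot$coords[, , f] %*% t(R)
  v0 <- coordinates(rot, atom_ref("A", 181, "CA")) -
    coordinates(rot, atom_ref("A", 167, "CA"))
  expect_lt(abs(v0[1]), 1e-9)  # now along Z
  back <- align_reference_to_x(rot, "A")
  v <- coordinates(back, atom_ref("A", 181, "CA")) -
    coordinates(back, atom_ref("A", 167, "CA"))
  expect_equal(v / sqrt(sum(v^2)), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(helix_angle(back, "A", back, fit = FALSE), 0, tolerance = 1e-9)
})

test_that("helix angle is 0 on the reference and exact on planted rotations", {
  expect_equal(helix_angle(reference, "A", reference), 0, tolerance = 1e-9)

  # plant a 15-degree in-plane (about Y) rotation of the whole monomer:
  # with fit = FALSE the projected angle is read off directly
  rot <- reference
  Ry <- oracle_rotation(c(0, 1, 0), -15)   # maps +X to (cos15, 0, sin15)
  rot$coords[, , 1] <- rot$coords[, , 1] %*% t(Ry)
  th <- helix_angle(rot, "A", reference, fit = FALSE)
  expect_equal(th, 15, tolerance = 1e-6)
  # with the monomer fit on, the global rotation is removed entirely
  expect_equal(helix_angle(rot, "A", reference, fit = TRUE), 0,
               tolerance = 1e-6)
})

test_that("out-of-plane rotation leaves the projected angle at 0", {
  rot <- reference
  Rz <- oracle_rotation(c(0, 0, 1), 15)    # tips helix into the X-Y plane
  rot$coords[, , 1] <- rot$coords[, , 1] %*% t(Rz)
  expect_equal(helix_angle(rot, "A", reference, fit = FALSE), 0,
               tolerance = 1e-9)
  Rx <- oracle_rotation(c(1, 0, 0), 30)    # rotation about X: +X unchanged
  rot$coords[, , 1] <- reference$coords[, , 1] %*% t(Rx)
  expect_equal(helix_angle(rot, "A", reference, fit = FALSE), 0,
               tolerance = 1e-9)
})

test_that("helix angle is invariant to global rigid motion under the fit", {
  set.seed(17)
  for (i in 1:5) {
    moved <- reference
    R <- oracle_rotation(rnorm(3), runif(1, 0, 120))
    t0 <- matrix(rnorm(3, sd = 30), nrow(moved$atoms), 3, byrow = TRUE)
    moved$coords[, , 1] <- moved$coords[, , 1] %*% t(R) + t0
    expect_equal(helix_angle(moved, "A", reference, fit = TRUE), 0,
                 tolerance = 1e-6)
  }
})

test_that("sign convention follows the Z component and is flippable", {
  rot <- reference
  Ry <- oracle_rotation(c(0, 1, 0), 10)    # maps +X to (cos10, 0, -sin10)
  rot$coords[, , 1] <- rot$coords[, , 1] %*% t(Ry)
  expect_equal(helix_angle(rot, "A", reference, fit = FALSE), -10,
               tolerance = 1e-6)
  expect_equal(helix_angle(rot, "A", reference, fit = FALSE, z_sign = -1),
               10, tolerance = 1e-6)
})

# --- distances -------------------------------------------------------------

test_that("distance series: 3-4-5 triangle, symmetry, rigid invariance", {
  ens <- toy_two_atom_ensemble(p1 = c(0, 0, 0), p2 = c(3, 4, 0))
  a <- atom_ref("A", 141, "CA"); b <- atom_ref("A", 171, "CG")
  expect_equal(distance_series(ens, a, b)$values, 5)
  expect_equal(distance_series(ens, b, a)$values, 5)
  R <- oracle_rotation(c(1, 1, 1), 77)
  ens$coords[, , 1] <- ens$coords[, , 1] %*% t(R) +
    matrix(c(5, 6, 7), 2, 3, byrow = TRUE)
  expect_equal(distance_series(ens, a, b)$values, 5, tolerance = 1e-9)
  expect_error(distance_series(ens, a, atom_ref("A", 999, "CA")), "frame 1")
})

test_that("R171 in/out swings anti-correlate the P141 and N181 distances", {
  out <- make_ensemble(ensemble_spec(n_frames = 300, seed = 42))
  dp <- distance_series(out$ensemble, atom_ref("A", 171, "CG"),
                        atom_ref("A", 141, "CA"))
  dm <- distance_series(out$ensemble, atom_ref("A", 171, "CG"),
                        atom_ref("A", 181, "CA"))
  expect_lt(cor(dp$values, dm$values), 0)
})

test_that("cross-chain pairs resolve (R171 of A vs H68 of adjacent B)", {
  out <- make_ensemble(ensemble_spec(n_frames = 5, seed = 43))
  d <- distance_series(out$ensemble, atom_ref("A", 171, "CG"),
                       atom_ref("B", 68, "CG"))
  expect_length(d$values, 5)
  expect_true(all(d$values > 0 & is.finite(d$values)))
})

test_that("dihedral_angle matches an analytic construction", {
  # four points with torsion phi about the +Y bond axis
  for (phi in c(-150, -60, 0, 60, 175)) {
    p1 <- c(1, 0, 0); p2 <- c(0, 0, 0); p3 <- c(0, 1, 0)
    p4 <- p3 + c(cos(phi * pi / 180), 0, sin(phi * pi / 180))
    expect_equal(dihedral_angle(p1, p2, p3, p4), phi, tolerance = 1e-9)
  }
})
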