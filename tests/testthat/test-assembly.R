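test_that("build_filament places subunits by twist and rise", {
  mono <- toy_shell_monomer()
  sym <- helical_symmetry(-90, 5)

  same <- build_filament(mono, sym, c(0, 0))
  expect_equal(same$atoms[, c("x", "y", "z")], mono$atoms[, c("x", "y", "z")],
               tolerance = 1e-12)

  one_atom <- fil_structure(data.frame(
    elety = "CA", resid = "ALA", chain = "A", resno = 1,
    x = 7, y = 0, z = 0, element = "C"))
  asm <- build_filament(one_atom, sym, c(0, 1))
  second <- asm$atoms[asm$atoms$subunit == 1, ]
  expect_equal(c(second$x, second$y, second$z), c(0, -7, 5),
               tolerance = 1e-12)

  sym2 <- helical_symmetry(-101.124, 4.848)
  asm10 <- build_filament(mono, sym2, c(0, 9))
  a <- asm10$atoms
  z0 <- mean(a$z[a$subunit == 0]); z9 <- mean(a$z[a$subunit == 9])
  expect_equal(z9 - z0, 9 * 4.848, tolerance = 1e-9)
  expect_identical(length(unique(a$chain)), 10L)
})

test_that("built assemblies satisfy the subunit-to-subunit mapping exactly", {
  mono <- toy_shell_monomer()
  sym <- helical_symmetry(-101.124, 4.848)
  asm <- build_filament(mono, sym, c(0, 7))
  a <- asm$atoms
  th <- sym$twist_deg * pi / 180
  for (k in 0:6) {
    ck <- as.matrix(a[a$subunit == k, c("x", "y", "z")])
    mapped <- cbind(ck[, 1] * cos(th) - ck[, 2] * sin(th),
                    ck[, 1] * sin(th) + ck[, 2] * cos(th),
                    ck[, 3] + sym$rise_ang)
    ck1 <- as.matrix(a[a$subunit == k + 1, c("x", "y", "z")])
    expect_lte(rmsd_fixed_frame(mapped, ck1), 1e-9)
  }
})

test_that("radial extents report inner and outer radii", {
  ring <- fil_structure(data.frame(
    elety = "CA", resid = "ALA", chain = "A", resno = 1:8,
    x = 10 * cos(seq(0, 2 * pi, length.out = 9)[-9]),
    y = 10 * sin(seq(0, 2 * pi, length.out = 9)[-9]),
    z = 0, element = "C"))
  expect_equal(unname(radial_extents(ring)), c(10, 10), tolerance = 1e-12)

  shell <- toy_shell_monomer(n = 50, r_in = 12.5, r_out = 37.5)
  ext <- radial_extents(shell)
  expect_equal(unname(ext), c(12.5, 37.5), tolerance = 1e-9)
  # diameters 25 and 75
  expect_equal(unname(2 * ext), c(25, 75), tolerance = 1e-9)
})

test_that("Kabsch superposition minimises RMSD", {
  set.seed(19)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_rmsd(a, a)$rmsd, 0)

  R <- euler_rot(0.4, 1.1, -0.7)
  b <- a %*% t(R) + matrix(c(3, -2, 5), 10, 3, byrow = TRUE)
  fit <- superpose_rmsd(a, b)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # fitted transform actually maps b onto a
  moved <- b %*% t(fit$rotation) +
    matrix(fit$translation, 10, 3, byrow = TRUE)
  expect_lt(rmsd_fixed_frame(a, moved), 1e-8)

  expect_error(superpose_rmsd(a[1:2, ], b[1:2, ]), "3 point")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose_rmsd(line, line + 1), "degenerate")
})

test_that("Kabsch agrees with a rotation-grid numerical oracle", {
  set.seed(29)
  for (i in 1:4) {
    a <- matrix(rnorm(12), 4, 3)
    b <- a
    b[1, ] <- b[1, ] + runif(3, -1, 1)    # displace one point
    b <- b %*% t(euler_rot(runif(1, 0, 2 * pi), runif(1, 0, pi),
                           runif(1, 0, 2 * pi)))
    expect_equal(superpose_rmsd(a, b)$rmsd, grid_search_rmsd(a, b),
                 tolerance = 1e-3)
  }
})

test_that("Kabsch agrees with the bio3d reference implementation", {
  set.seed(37)
  a <- matrix(rnorm(24), 8, 3)
  b <- a + matrix(rnorm(24, 0, 0.5), 8, 3)
  ours <- superpose_rmsd(a, b)$rmsd
  fitted <- bio3d::fit.xyz(as.numeric(t(a)), as.numeric(t(b)),
                           fixed.inds = 1:24, mobile.inds = 1:24)
  ref <- bio3d::rmsd(as.numeric(t(a)), fitted)
  expect_equal(ours, ref, tolerance = 1e-3)  # bio3d rounds its RMSD
})

test_that("superposition is symmetric, rigid-motion invariant, and bounded", {
  set.seed(41)
  a <- matrix(rnorm(21), 7, 3)
  b <- a + matrix(rnorm(21, 0, 0.3), 7, 3)
  r_ab <- superpose_rmsd(a, b)$rmsd
  expect_equal(r_ab, superpose_rmsd(b, a)$rmsd, tolerance = 1e-8)
  moved <- b %*% t(euler_rot(1, 0.5, 2)) +
    matrix(c(10, -4, 2), 7, 3, byrow = TRUE)
  expect_equal(superpose_rmsd(a, moved)$rmsd, r_ab, tolerance = 1e-8)
  expect_lte(r_ab, rmsd_fixed_frame(a, b))
})

test_that("fixed-frame RMSD is plain arithmetic", {
  p <- matrix(c(0, 0, 0), 1, 3)
  q <- matrix(c(3, 4, 0), 1, 3)
  expect_equal(rmsd_fixed_frame(rbind(p, p, p), rbind(q, q, q)), 5)
  set.seed(43)
  a <- matrix(rnorm(15), 5, 3); b <- matrix(rnorm(15), 5, 3)
  expect_equal(rmsd_fixed_frame(a, b),
               sqrt(mean(rowSums((a - b)^2))), tolerance = 1e-12)
})

test_that("atom pairing matches by residue number and atom name", {
  s1 <- fil_structure(data.frame(
    elety = "CA", resid = "ALA", chain = "A", resno = c(1, 2, 3),
    x = 1:3, y = 0, z = 0, element = "C"))
  s2 <- fil_structure(data.frame(
    elety = "CA", resid = "ALA", chain = "A", resno = c(2, 3, 4),
    x = 4:6, y = 0, z = 0, element = "C"))
  p <- pair_atoms(s1, s2)
  expect_identical(nrow(p$xyz_a), 2L)
  expect_setequal(p$unpaired, c(1, 4))
})
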