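test_that("truncated-ellipsoid fixture is watertight with analytic cavity volume", {
  spec <- ellipsoid_spec(target_edge = 6)
  mesh <- make_truncated_ellipsoid_mesh(spec)
  expect_true(validate_labeled_mesh(mesh))
  expect_setequal(names(mesh$surface_patches), c("endo", "epi", "base"))
  expect_true(all(mesh$h_e > 0))
  # quadrature oracle: solid-of-revolution volume of the truncated spheroid
  Va <- integrate(function(z) pi * spec$a_endo^2 * (1 - z^2 / spec$c_endo^2),
                  -spec$c_endo, spec$trunc_height)$value / 1000
  V <- cavity_volume(mesh)
  expect_lt(abs(V - Va) / Va, 0.02)
  # refinement reduces the cavity-volume error
  V2 <- cavity_volume(make_truncated_ellipsoid_mesh(
    ellipsoid_spec(target_edge = 3)))
  expect_lt(abs(V2 - Va), abs(V - Va))
})

test_that("degenerate ellipsoid specs are rejected", {
  expect_error(ellipsoid_spec(a_endo = 30, a_epi = 25), "radii")
  expect_error(ellipsoid_spec(a_endo = 25, a_epi = 25), "radii")
  expect_error(ellipsoid_spec(trunc_height = 60), "truncation")
  expect_error(ellipsoid_spec(target_edge = -1), "positive")
})

test_that("box mesh has exact volume and complete patches", {
  mesh <- make_box_mesh(2, 1, 3, lx = 2, ly = 0.5, lz = 1.5)
  expect_true(validate_labeled_mesh(mesh))
  expect_equal(sum(heartfem:::tet_signed_volumes(mesh$vertices, mesh$tets)),
               2 * 0.5 * 1.5, tolerance = 1e-12)
  expect_setequal(names(mesh$surface_patches),
                  c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax"))
})

test_that("harmonic transmural coordinate matches the spherical-shell solution", {
  # hemispherical shell radii 1 -> 2, truncated at the equator where the
  # radial harmonic solution has zero normal derivative
  shell <- make_truncated_ellipsoid_mesh(ellipsoid_spec(
    a_endo = 1, c_endo = 1, a_epi = 2, c_epi = 2, trunc_height = 0,
    target_edge = 0.25))
  tm <- transmural_coordinate(shell)
  expect_identical(unname(tm[patch_nodes(shell, "endo")]),
                   rep(0, length(patch_nodes(shell, "endo"))))
  expect_identical(unname(tm[patch_nodes(shell, "epi")]),
                   rep(1, length(patch_nodes(shell, "epi"))))
  # maximum principle
  expect_true(all(tm >= 0 & tm <= 1))
  inner <- setdiff(seq_len(nrow(shell$vertices)),
                   c(patch_nodes(shell, "endo"), patch_nodes(shell, "epi")))
  expect_true(all(tm[inner] > 0 & tm[inner] < 1))
  # analytic harmonic oracle (1/r - 1)/(1/2 - 1)
  r <- sqrt(rowSums(shell$vertices^2))
  expect_lt(max(abs(tm - (1 / r - 1) / (1 / 2 - 1))), 0.03)
  expect_error(transmural_coordinate(make_box_mesh(1, 1, 1)), "patch")
})

test_that("ventricular fiber helix angle varies linearly across the wall", {
  mesh <- make_truncated_ellipsoid_mesh(ellipsoid_spec(target_edge = 6))
  tm <- transmural_coordinate(mesh)
  fib <- assign_ventricular_fibers(mesh, tm, endo_angle = 60, epi_angle = -60)
  # per-element transmural value reproduces the linear helix rule
  t_e <- apply(mesh$tets, 1, function(nd) mean(tm[nd]))
  expect_equal(fib$helix_angle, 60 + t_e * (-120), tolerance = 1e-9)
  # at the limits of the rule: t = 0 -> +60, t = 0.5 -> 0, t = 1 -> -60
  mock <- c(0, 0.5, 1)
  expect_equal(60 + mock * (-120), c(60, 0, -60))
  # triads orthonormal everywhere
  expect_lt(triad_orthonormality_error(fib$triads), 1e-8)
  # fiber lies in the plane perpendicular to the transmural sheet direction
  dot_fs <- rowSums(fib$triads[, 1:3] * fib$triads[, 4:6])
  expect_lt(max(abs(dot_fs)), 1e-8)
  expect_error(assign_ventricular_fibers(mesh, tm, axis = c(0, 0, 0)), "axis")
})

test_that("atrial fiber rule blends circumferential and longitudinal fields", {
  mesh <- make_truncated_ellipsoid_mesh(
    ellipsoid_spec(chamber = "la", a_endo = 18, c_endo = 20, a_epi = 21,
                   c_epi = 23, trunc_height = 2, target_edge = 4))
  tm <- transmural_coordinate(mesh)
  f0 <- assign_atrial_fibers(mesh, tm, blend = 0)
  # pure circumferential: fibers perpendicular to the apex-base axis
  expect_lt(max(abs(f0$triads[, 3])), 1e-6)
  expect_equal(unname(rowSums(f0$triads[, 1:3]^2)), rep(1, nrow(mesh$tets)),
               tolerance = 1e-12)
  f1 <- assign_atrial_fibers(mesh, tm, blend = 1)
  # pure longitudinal vs pure circumferential are orthogonal fields
  dots <- rowSums(f0$triads[, 1:3] * f1$triads[, 1:3])
  expect_lt(max(abs(dots)), 1e-8)
  expect_lt(triad_orthonormality_error(f1$triads), 1e-8)
})

test_that("mesh round-trips through Gmsh and VTU formats", {
  mesh <- make_truncated_ellipsoid_mesh(ellipsoid_spec(
    n_trans = 1, n_long = 4, n_circ = 8))
  f <- tempfile(fileext = ".msh")
  write_msh(mesh, f)
  back <- read_msh(f)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-9)
  expect_identical(back$tets, mesh$tets)
  expect_setequal(names(back$surface_patches), names(mesh$surface_patches))
  expect_identical(dim(back$surface_patches$endo), dim(mesh$surface_patches$endo))
  fib <- assign_ventricular_fibers(mesh)
  v <- tempfile(fileext = ".vtu")
  tm <- transmural_coordinate(mesh)
  write_vtu(mesh, v, point_data = list(transmural = tm),
            cell_data = list(fiber = fib$triads[, 1:3]))
  rb <- read_vtu(v)
  expect_equal(rb$vertices, mesh$vertices, tolerance = 1e-8)
  expect_identical(rb$tets, mesh$tets)
  expect_equal(rb$point_data$transmural, tm, tolerance = 1e-8)
  expect_equal(rb$cell_data$fiber, fib$triads[, 1:3], tolerance = 1e-8)
})
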