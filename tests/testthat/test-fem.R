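test_that("residual vanishes in the stress-free reference state", {
  mesh <- make_box_mesh(1, 1, 1)
  mesh$endo_patches <- c(lv = "zmin")
  prob <- fem_problem(mesh, identity_triads(mesh), robin_patch = "zmax")
  res <- assemble_residual(mech_state(mesh), prob, c(lv = 0))
  expect_equal(res, rep(0, length(res)), tolerance = 1e-14)
  # missing chamber pressure is an error
  expect_error(assemble_residual(mech_state(mesh), prob), "pressure")
})

test_that("Robin traction follows the normal/tangential projector algebra", {
  rp <- robin_params(k_n = 2, k_t = 0.3, c_n = 1.5, c_t = 0.1)
  N <- c(0, 0, 1)
  expect_equal(robin_traction(c(0, 0, 0), c(0, 0, 0), N, rp), c(0, 0, 0))
  # normal displacement -> -k_n * delta * N
  expect_equal(robin_traction(0.4 * N, c(0, 0, 0), N, rp), -2 * 0.4 * N)
  # tangential displacement -> -k_t u
  ut <- c(0.3, -0.2, 0)
  expect_equal(robin_traction(ut, c(0, 0, 0), N, rp), -0.3 * ut)
  # damping acts on velocity with the same split
  expect_equal(robin_traction(c(0, 0, 0), 0.2 * N + ut, N, rp),
               -1.5 * 0.2 * N - 0.1 * ut)
  expect_error(robin_traction(ut, ut, c(0, 0, 2), rp), "unit")
  # dissipation of the assembled damping matrix is non-negative
  mesh <- make_box_mesh(1, 1, 1)
  prob <- fem_problem(mesh, identity_triads(mesh), robin = rp,
                      robin_patch = "zmax")
  set.seed(21)
  for (k in 1:5) {
    v <- rnorm(4 * nrow(mesh$vertices))
    expect_gte(as.numeric(t(v) %*% prob$C_robin %*% v), 0)
  }
})

test_that("assembled tangent matches finite differences of the residual", {
  mesh <- make_box_mesh(1, 1, 1)
  mesh$endo_patches <- c(lv = "zmin")
  prob <- fem_problem(mesh, identity_triads(mesh), robin_patch = "zmax")
  N <- nrow(mesh$vertices)
  set.seed(22)
  st <- mech_state(mesh, t = 150, dt = 1)
  st$u <- rnorm(3 * N, sd = 0.01)
  st$p <- rnorm(N, sd = 1)
  st$u_prev <- rnorm(3 * N, sd = 0.005)
  pr <- c(lv = 0.7)
  J <- as.matrix(fem_residual(prob, st, pr, want_jac = TRUE)$jac)
  Jfd <- fd_jacobian(prob, st, pr)
  expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-5)
})

test_that("single-element uniaxial stretch matches the incompressible Fung solution", {
  mesh <- make_box_mesh(2, 2, 2)
  lam <- 1.05
  prob <- fem_problem(mesh, identity_triads(mesh),
                      active = active_params(T_ref = 0), robin_patch = NULL)
  prob$dirichlet <- rbind(
    dirichlet_constraints(mesh, "xmin", 1, 0),
    dirichlet_constraints(mesh, "xmax", 1, lam - 1),
    dirichlet_constraints(mesh, "ymin", 2, 0),
    dirichlet_constraints(mesh, "zmin", 3, 0))
  sol <- newton_solve(prob, mech_state(mesh))
  expect_true(sol$converged)
  # semi-analytic oracle: F = diag(lam, lam^-1/2, lam^-1/2), pressure
  # eliminated by zero lateral Cauchy stress
  S <- passive_first_pk(diag(c(lam, lam^-0.5, lam^-0.5)))$S
  sig_ana <- lam^2 * S[1, 1] - lam^-1 * S[2, 2]
  res <- fem_residual(prob, sol$state, want_jac = FALSE)$res
  nd <- patch_nodes(mesh, "xmax")
  sig_fe <- sum(res[3 * (nd - 1) + 1]) / (lam^-0.5)^2  # deformed area
  expect_lt(abs(sig_fe - sig_ana) / abs(sig_ana), 1e-3)
  # discrete incompressibility is exact for this homogeneous state
  g <- heartfem:::tet_grads(mesh)
  Fall <- heartfem:::element_def_gradients(mesh, sol$state$u, g)
  Js <- apply(Fall, 1, function(Fm) det(matrix(Fm, 3, 3)))
  expect_lt(max(abs(Js - 1)), 1e-10)
})

test_that("stabilization vanishes for constant pressure and switches off with alpha", {
  mesh <- make_box_mesh(2, 2, 1)
  N <- nrow(mesh$vertices)
  expect_equal(stabilization_contribution(rep(3.7, N), mesh),
               rep(0, N), tolerance = 1e-12)
  K0 <- stabilization_matrix(mesh, stab_params(alpha = 0))
  expect_equal(Matrix::norm(K0, "F"), 0)
  # non-constant pressure is penalized
  p <- mesh$vertices[, 1]
  expect_gt(sum(p * stabilization_contribution(p, mesh)), 0)
})

test_that("uniform follower pressure on all faces is an exact discrete solution", {
  # cube loaded by the same cavity pressure q on every face: u = 0 with a
  # constant pressure multiplier is the exact solution of the stabilized
  # discrete system
  mesh <- make_box_mesh(2, 2, 2)
  mesh$endo_patches <- c(cav = "all")
  mesh$surface_patches$all <- do.call(rbind, mesh$surface_patches[
    c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")])
  mesh$surface_patches[c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")] <- NULL
  prob <- fem_problem(mesh, identity_triads(mesh),
                      active = active_params(T_ref = 0), robin_patch = NULL)
  # pin rigid modes at three corners (consistent with u = 0)
  corner <- function(x, y, z) which(colSums(abs(t(mesh$vertices) - c(x, y, z))) < 1e-12)
  prob$dirichlet <- data.frame(
    node = c(rep(corner(0, 0, 0), 3), rep(corner(1, 0, 0), 2), corner(0, 1, 0)),
    comp = c(1, 2, 3, 2, 3, 3), value = 0)
  q <- 2.5
  sol <- newton_solve(prob, mech_state(mesh), c(cav = q))
  expect_true(sol$converged)
  expect_lt(max(abs(sol$state$u)), 1e-9)
  # hydrostatic compression: Cauchy stress -q I, so the pressure
  # multiplier equals +q everywhere
  expect_equal(unname(sol$state$p), rep(q, nrow(mesh$vertices)),
               tolerance = 1e-8)
})

test_that("cavity volume integrates closed and capped surfaces correctly", {
  # unit sphere, divergence-theorem oracle 4*pi/3
  ss <- sphere_surface(1, 16, 32)
  V <- heartfem:::closed_surface_volume_mm3(ss$vertices, ss$tris)
  expect_lt(abs(V - 4 * pi / 3) / (4 * pi / 3), 0.02)
  # refinement converges
  ss2 <- sphere_surface(1, 32, 64)
  V2 <- heartfem:::closed_surface_volume_mm3(ss2$vertices, ss2$tris)
  expect_lt(abs(V2 - 4 * pi / 3), abs(V - 4 * pi / 3))
  # uniform scaling -> lambda^3; rigid translation -> unchanged
  mesh <- make_truncated_ellipsoid_mesh(ellipsoid_spec(n_trans = 1,
                                                       n_long = 5, n_circ = 10))
  V0 <- cavity_volume(mesh)
  u_scale <- as.vector(t(mesh$vertices * (1.1 - 1)))
  expect_equal(cavity_volume(mesh, "lv", u_scale), 1.1^3 * V0,
               tolerance = 1e-10)
  u_shift <- rep(c(5, -3, 2), nrow(mesh$vertices))
  expect_equal(cavity_volume(mesh, "lv", u_shift), V0, tolerance = 1e-10)
  expect_error(cavity_volume(mesh, "rv"), "unknown chamber")
})

test_that("Newton solver converges immediately at zero load and honors constraints", {
  mesh <- make_truncated_ellipsoid_mesh(ellipsoid_spec(n_trans = 1,
                                                       n_long = 5, n_circ = 10))
  fib <- assign_ventricular_fibers(mesh)
  prob <- apply_dirichlet(fem_problem(mesh, fib), "base")
  sol <- newton_solve(prob, mech_state(mesh), c(lv = 0))
  expect_true(sol$converged)
  expect_lte(sol$iterations, 1)
  sol2 <- newton_solve(prob, mech_state(mesh), c(lv = 1))
  expect_true(sol2$converged)
  base <- patch_nodes(mesh, "base")
  expect_identical(unname(sol2$state$u[rep(3 * (base - 1), each = 3) + 1:3]),
                   rep(0, 3 * length(base)))
  # superlinear contraction in the final iterations of full Newton:
  # successive reduction factors themselves shrink fast
  rn <- sol2$res_norms
  k <- length(rn)
  expect_lt(rn[k] / rn[k - 1], 0.01 * rn[k - 1] / rn[k - 2])
})

test_that("free-floating stiffness has exactly six zero-energy modes", {
  mesh <- make_box_mesh(1, 1, 1)
  prob <- fem_problem(mesh, identity_triads(mesh),
                      active = active_params(T_ref = 0), robin_patch = NULL,
                      stab = stab_params(alpha = 0))
  N <- nrow(mesh$vertices)
  J <- as.matrix(fem_residual(prob, mech_state(mesh), want_jac = TRUE)$jac)
  Kuu <- J[1:(3 * N), 1:(3 * N)]
  ev <- sort(abs(eigen((Kuu + t(Kuu)) / 2, symmetric = TRUE,
                       only.values = TRUE)$values))
  expect_lt(ev[6], 1e-8)
  expect_gt(ev[7], 1)
  # Robin springs alone restore solvability (rank check at reference)
  prob2 <- fem_problem(mesh, identity_triads(mesh),
                       active = active_params(T_ref = 0),
                       robin_patch = "zmax", stab = stab_params(alpha = 0))
  J2 <- as.matrix(fem_residual(prob2, mech_state(mesh), want_jac = TRUE)$jac)
  K2 <- J2[1:(3 * N), 1:(3 * N)]
  ev2 <- sort(abs(eigen((K2 + t(K2)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values))
  expect_gt(ev2[1], 1e-6)
})

test_that("empty Dirichlet patch warns instead of failing", {
  mesh <- make_box_mesh(1, 1, 1)
  mesh$surface_patches$ghost <- mesh$surface_patches$zmin[0, , drop = FALSE]
  expect_warning(dirichlet_constraints(mesh, "ghost"), "Robin")
})
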