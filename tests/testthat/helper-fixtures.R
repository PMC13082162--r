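# shared fixtures, built once per test run

identity_triads <- function(mesh) {
  M <- nrow(mesh$tets)
  microstructure_field(matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), M),
                              M, 9, byrow = TRUE))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# coarse single-3D-LV fixture used by the coupled tests
lv_fixture_mesh <- function() cached("lv_mesh", {
  make_truncated_ellipsoid_mesh(ellipsoid_spec(n_trans = 1, n_long = 6,
                                               n_circ = 12))
})

lv_fixture_fibers <- function() cached("lv_fibers", {
  assign_ventricular_fibers(lv_fixture_mesh())
})

lv_fixture_config <- function(...) {
  simulation_config(mesh = lv_fixture_mesh(), fibers = lv_fixture_fibers(),
                    chambers_3d = "lv", dt = 4, ...)
}

# the desk-scale baseline and reduced-LV-contractility coupled runs are
# shared across several tests; computed once
baseline_coupled_run <- function() cached("baseline_run", {
  suppressWarnings(run_cardiac_cycles(lv_fixture_config(n_cycles = 5)))
})

ischemic_coupled_run <- function() cached("ischemic_run", {
  cfg <- apply_ischemia(lv_fixture_config(n_cycles = 3), "lv", 0.25)
  suppressWarnings(run_cardiac_cycles(cfg))
})

# k-th cycle slice of a multi-cycle beat record
record_cycle <- function(rec, k, cycle_period = 800) {
  dt <- rec$time[2] - rec$time[1]
  steps <- round(cycle_period / dt)
  idx <- ((k - 1) * steps + 1):(k * steps)
  beat_record(rec$time[idx], rec$pressure[idx, , drop = FALSE],
              rec$volume[idx, , drop = FALSE])
}

# dense finite-difference Jacobian of the assembled residual
fd_jacobian <- function(problem, state, pressures, h = 1e-6) {
  N <- nrow(problem$mesh$vertices)
  x0 <- c(state$u, state$p)
  J <- matrix(0, 4 * N, 4 * N)
  for (d in seq_len(4 * N)) {
    xp <- x0; xp[d] <- xp[d] + h
    xm <- x0; xm[d] <- xm[d] - h
    stp <- state; stp$u <- xp[1:(3 * N)]; stp$p <- xp[3 * N + 1:N]
    stm <- state; stm$u <- xm[1:(3 * N)]; stm$p <- xm[3 * N + 1:N]
    rp <- fem_residual(problem, stp, pressures, want_jac = FALSE)$res
    rm_ <- fem_residual(problem, stm, pressures, want_jac = FALSE)$res
    J[, d] <- (rp - rm_) / (2 * h)
  }
  J
}

# lat-long triangulation of a sphere surface (closed, outward-oriented)
sphere_surface <- function(r = 1, n_lat = 16, n_lon = 32) {
  verts <- rbind(c(0, 0, r))
  for (i in seq_len(n_lat - 1)) {
    th <- pi * i / n_lat
    ph <- 2 * pi * (0:(n_lon - 1)) / n_lon
    verts <- rbind(verts, cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph),
                                r * cos(th)))
  }
  verts <- rbind(verts, c(0, 0, -r))
  vid <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  tris <- NULL
  for (j in 1:n_lon) tris <- rbind(tris, c(1L, vid(1, j), vid(1, j + 1)))
  for (i in 1:(n_lat - 2)) for (j in 1:n_lon) {
    tris <- rbind(tris,
                  c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1)),
                  c(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1)))
  }
  south <- nrow(verts)
  for (j in 1:n_lon)
    tris <- rbind(tris, c(south, vid(n_lat - 1, j + 1), vid(n_lat - 1, j)))
  list(vertices = verts, tris = tris)
}

# isotropic passive parameters (all exponents equal makes Q frame-invariant)
iso_passive <- function() passive_params(C = 2, b_ff = 8, b_xx = 8, b_fx = 8)

# semi-analytic incompressible isotropic thick-sphere inflation: internal
# pressure as a function of the deformed inner radius, by 1D quadrature of
# the through-wall circumferential/radial stress difference
sphere_inflation_pressure <- function(a, A, B, passive) {
  W_iso <- function(lam) {
    Er <- (lam^-4 - 1) / 2; Et <- (lam^2 - 1) / 2
    0.5 * passive$C * expm1(passive$b_xx * (Er^2 + 2 * Et^2))
  }
  b <- (B^3 + a^3 - A^3)^(1 / 3)
  stats::integrate(function(r) {
    R <- (r^3 - a^3 + A^3)^(1 / 3)
    lam <- r / R
    h <- 1e-6
    lam * (W_iso(lam + h) - W_iso(lam - h)) / (2 * h) / r
  }, a, b, rel.tol = 1e-10)$value
}

# stabilized P1-P1 hemisphere-shell inflation; returns mean endocardial
# radial displacement and solver info
solve_shell_inflation <- function(edge, A = 10, B = 15, P_int = 1,
                                  alpha = 1, max_depth = 6) {
  passive <- iso_passive()
  mesh <- make_truncated_ellipsoid_mesh(ellipsoid_spec(
    a_endo = A, c_endo = A, a_epi = B, c_epi = B, trunc_height = 0,
    target_edge = edge))
  prob <- fem_problem(mesh, identity_triads(mesh), passive = passive,
                      active = active_params(T_ref = 0), robin_patch = NULL,
                      stab = stab_params(alpha = alpha))
  # roller base plane, apex axis pinned transversally, one azimuthal pin:
  # the exact radial solution satisfies all of these
  dc <- dirichlet_constraints(mesh, "base", 3, 0)
  ax <- which(sqrt(mesh$vertices[, 1]^2 + mesh$vertices[, 2]^2) < 1e-8)
  dc <- rbind(dc, data.frame(node = rep(ax, each = 2),
                             comp = rep(1:2, length(ax)), value = 0))
  br <- patch_nodes(mesh, "base")
  onx <- br[abs(mesh$vertices[br, 2]) < 1e-8 & mesh$vertices[br, 1] > 0][1]
  dc <- rbind(dc, data.frame(node = onx, comp = 2, value = 0))
  prob$dirichlet <- dc
  sol <- solve_mech_pressures(prob, mech_state(mesh), c(lv = P_int),
                              max_depth = max_depth)
  endo <- patch_nodes(mesh, "endo")
  um <- matrix(sol$state$u, ncol = 3, byrow = TRUE)
  xr <- mesh$vertices[endo, ]
  ur <- rowSums(um[endo, ] * xr / sqrt(rowSums(xr^2)))
  list(mesh = mesh, prob = prob, sol = sol, u_r = mean(ur))
}
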