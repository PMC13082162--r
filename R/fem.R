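#' Mechanical state of the wall at one time level
#'
#' Nodal displacement `u` (mm, interleaved x1 y1 z1 x2 ...), nodal pressure
#' Lagrange multiplier `p` (kPa), the previous-step displacement (used for
#' the backward-Euler velocity in the Robin damping term), time and step.
#'
#' @param mesh a [labeled_mesh()]
#' @param u,p,u_prev optional initial fields (default zero)
#' @param t time (ms)
#' @param dt time step (ms)
#' @return object of class `mech_state`
#' @export
mech_state <- function(mesh, u = NULL, p = NULL, u_prev = NULL, t = 0, dt = 1) {
  N <- nrow(mesh$vertices)
  if (is.null(u)) u <- numeric(3 * N)
  if (is.null(p)) p <- numeric(N)
  if (is.null(u_prev)) u_prev <- u
  stopifnot(length(u) == 3 * N, length(p) == N, length(u_prev) == 3 * N, dt > 0)
  structure(list(u = u, p = p, u_prev = u_prev, t = t, dt = dt),
            class = "mech_state")
}

#' Robin spring-damper traction (pointwise)
#'
#' `traction = -(K_epi u + C_epi u_dot)` with the anisotropic tensors
#' `K_epi = k_n N (x) N + k_t (I - N (x) N)` (likewise `C_epi`), `N` the unit
#' outward reference normal.
#'
#' @param u displacement (mm), length 3
#' @param u_dot velocity (mm/ms), length 3
#' @param N unit outward normal
#' @param params [robin_params()]
#' @return traction vector (kPa)
#' @export
robin_traction <- function(u, u_dot, N, params = robin_params()) {
  if (abs(sum(N^2) - 1) > 1e-8) stop("N must be a unit vector")
  nn <- outer(N, N)
  K <- params$k_n * nn + params$k_t * (diag(3) - nn)
  C <- params$c_n * nn + params$c_t * (diag(3) - nn)
  -as.vector(K %*% u + C %*% u_dot)
}

#' Define a mechanics problem on a labeled mesh
#'
#' Bundles the mesh, microstructure, material/boundary-condition parameters
#' and constraints, and precomputes the constant matrices (Robin surface
#' stiffness/damping, pressure stabilization).
#'
#' @param mesh a [labeled_mesh()]
#' @param fibers a [microstructure_field()] (one triad per element)
#' @param passive [passive_params()]
#' @param active [active_params()]; set `T_ref = 0` for passive-only problems
#' @param robin [robin_params()] applied on `robin_patch`
#' @param robin_patch patch name for the Robin boundary (NULL to disable)
#' @param dirichlet data.frame with columns `node`, `comp` (1:3), `value`;
#'   see [dirichlet_constraints()]
#' @param stab [stab_params()]
#' @param act_multiplier per-element contractility multiplier (default 1);
#'   used by the ischemia protocol
#' @param cycle_period cardiac cycle length (ms) used to wrap activation time
#' @return object of class `fem_problem`
#' @export
fem_problem <- function(mesh, fibers, passive = passive_params(),
                        active = active_params(), robin = robin_params(),
                        robin_patch = "epi", dirichlet = NULL,
                        stab = stab_params(),
                        act_multiplier = 1, cycle_period = 800) {
  stopifnot(inherits(mesh, "labeled_mesh"), inherits(fibers, "microstructure_field"))
  M <- nrow(mesh$tets)
  if (nrow(fibers$triads) != M) stop("fibers and mesh element counts differ")
  act_multiplier <- rep_len(act_multiplier, M)
  N <- nrow(mesh$vertices)
  ndof <- 4 * N
  if (!is.null(robin_patch) && !is.null(robin) &&
      robin_patch %in% names(mesh$surface_patches)) {
    rb <- robin_surface_matrices(mesh, robin_patch, robin)
  } else {
    rb <- list(K = Matrix::sparseMatrix(i = integer(), j = integer(),
                                        x = numeric(), dims = c(ndof, ndof)),
               C = Matrix::sparseMatrix(i = integer(), j = integer(),
                                        x = numeric(), dims = c(ndof, ndof)))
  }
  K_stab <- stabilization_matrix(mesh, stab, passive)
  Kc <- as(K_stab + rb$K, "TsparseMatrix")
  Cc <- as(rb$C, "TsparseMatrix")
  structure(list(
    mesh = mesh, triads = fibers$triads, passive = passive, active = active,
    robin = robin, robin_patch = robin_patch,
    dirichlet = dirichlet, stab = stab,
    act_multiplier = act_multiplier, cycle_period = cycle_period,
    K_robin = rb$K, C_robin = rb$C, K_stab = K_stab,
    # triplet forms of the constant matrices for fast re-assembly
    Kc_T = list(i = Kc@i + 1L, j = Kc@j + 1L, x = Kc@x),
    Cc_T = list(i = Cc@i + 1L, j = Cc@j + 1L, x = Cc@x)),
    class = "fem_problem")
}

#' Dirichlet constraints for all components of a surface patch
#'
#' In the idealized fixtures the flat basal annulus stands in for the
#' truncated great-vessel rim, where displacement is fixed to zero.
#'
#' @param mesh a [labeled_mesh()]
#' @param patch patch name
#' @param comps displacement components to constrain (subset of 1:3)
#' @param value prescribed value (mm), recycled
#' @return data.frame with columns node, comp, value
#' @export
dirichlet_constraints <- function(mesh, patch, comps = 1:3, value = 0) {
  nodes <- patch_nodes(mesh, patch)
  if (!length(nodes)) {
    warning("empty Dirichlet patch '", patch,
            "': model is restrained only by Robin terms")
    return(data.frame(node = integer(), comp = integer(), value = numeric()))
  }
  data.frame(node = rep(nodes, each = length(comps)),
             comp = rep(comps, times = length(nodes)),
             value = value)
}

#' Attach Dirichlet constraints to a problem
#'
#' @param problem a [fem_problem()]
#' @param patch patch name whose nodes are constrained
#' @param comps components (1:3)
#' @param value prescribed displacement (mm)
#' @return the modified problem
#' @export
apply_dirichlet <- function(problem, patch, comps = 1:3, value = 0) {
  dc <- dirichlet_constraints(problem$mesh, patch, comps, value)
  problem$dirichlet <- rbind(problem$dirichlet, dc)
  problem
}

# assemble Robin surface stiffness/damping matrices (constant; reference
# normals, exact integration of the linear traction with the triangle
# consistent mass matrix)
robin_surface_matrices <- function(mesh, patch, params) {
  tris <- mesh$surface_patches[[patch]]
  N <- nrow(mesh$vertices)
  ndof <- 4 * N
  nt <- nrow(tris)
  cap <- nt * 81L
  iK <- jK <- integer(cap); xK <- xC <- numeric(cap); n <- 0L
  Mloc <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2) / 12, 3, 3)
  for (r in seq_len(nt)) {
    v <- mesh$vertices[tris[r, ], ]
    av <- pracma_cross(v[2, ] - v[1, ], v[3, ] - v[1, ]) / 2
    A <- sqrt(sum(av^2))
    nrm <- av / A
    nn <- outer(nrm, nrm)
    Kd <- params$k_n * nn + params$k_t * (diag(3) - nn)
    Cd <- params$c_n * nn + params$c_t * (diag(3) - nn)
    for (a in 1:3) for (b in 1:3) {
      w <- A * Mloc[a, b]
      for (i in 1:3) for (k in 1:3) {
        n <- n + 1L
        iK[n] <- 3L * (tris[r, a] - 1L) + i
        jK[n] <- 3L * (tris[r, b] - 1L) + k
        xK[n] <- w * Kd[i, k]
        xC[n] <- w * Cd[i, k]
      }
    }
  }
  list(K = Matrix::sparseMatrix(i = iK[1:n], j = jK[1:n], x = xK[1:n],
                                dims = c(ndof, ndof)),
       C = Matrix::sparseMatrix(i = iK[1:n], j = jK[1:n], x = xC[1:n],
                                dims = c(ndof, ndof)))
}

#' Pressure-stabilization matrix
#'
#' Element-wise pressure-Laplacian \eqn{\sum_e (\alpha h_e^2/2\mu) \int_e
#' \nabla p \cdot \nabla \delta p \, dV} assembled on the pressure dofs.
#' Vanishes on element-wise constant pressure fields; with `alpha = 0` the
#' formulation reduces to the unstabilized mixed form.
#'
#' @param mesh a [labeled_mesh()]
#' @param stab [stab_params()]
#' @param passive [passive_params()] (supplies the default shear modulus)
#' @return sparse matrix over the full dof vector (u block empty)
#' @export
stabilization_matrix <- function(mesh, stab = stab_params(),
                                 passive = passive_params()) {
  mu <- resolve_stab_mu(stab, passive)
  g <- tet_grads(mesh)
  M <- nrow(mesh$tets)
  N <- nrow(mesh$vertices)
  ii <- jj <- integer(16 * M); xx <- numeric(16 * M); n <- 0L
  for (e in seq_len(M)) {
    coef <- stab$alpha * mesh$h_e[e]^2 / (2 * mu)
    Ge <- g$G[e, , ]
    Ke <- coef * g$vol[e] * (Ge %*% t(Ge))
    nd <- 3L * N + mesh$tets[e, ]
    ii[n + 1:16] <- rep(nd, each = 4)
    jj[n + 1:16] <- rep(nd, times = 4)
    xx[n + 1:16] <- as.vector(Ke)
    n <- n + 16L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(4 * N, 4 * N))
}

#' Stabilization contribution to the residual
#'
#' @param p nodal pressure field
#' @param mesh a [labeled_mesh()]
#' @param stab [stab_params()]
#' @param passive [passive_params()]
#' @return residual contribution on the pressure dofs (length N)
#' @export
stabilization_contribution <- function(p, mesh, stab = stab_params(),
                                       passive = passive_params()) {
  N <- nrow(mesh$vertices)
  K <- stabilization_matrix(mesh, stab, passive)
  as.vector(K %*% c(numeric(3 * N), p))[3 * N + seq_len(N)]
}

# follower cavity-pressure load: residual contribution and tangent triplets.
# tris are oriented outward from the solid; the cavity pressure traction on
# the wall is -P n_solid, entering the residual (internal - external) as
# +P/6 cross(x2-x1, x3-x1) per node of each deformed triangle.
follower_load <- function(verts_def, tris, P, N, want_jac) {
  res <- numeric(4 * N)
  nt <- nrow(tris)
  skew <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  if (want_jac) {
    cap <- nt * 81L
    ii <- jj <- integer(cap); xx <- numeric(cap); n <- 0L
  }
  for (r in seq_len(nt)) {
    nd <- tris[r, ]
    x1 <- verts_def[nd[1], ]; x2 <- verts_def[nd[2], ]; x3 <- verts_def[nd[3], ]
    f <- (P / 6) * pracma_cross(x2 - x1, x3 - x1)
    for (a in 1:3) res[3 * (nd[a] - 1) + 1:3] <- res[3 * (nd[a] - 1) + 1:3] + f
    if (want_jac) {
      blocks <- list(
        (P / 6) * skew(x3 - x2),    # d f / d x1
        -(P / 6) * skew(x3 - x1),   # d f / d x2
        (P / 6) * skew(x2 - x1))    # d f / d x3
      for (a in 1:3) for (b in 1:3) {
        B <- blocks[[b]]
        for (i in 1:3) for (k in 1:3) {
          n <- n + 1L
          ii[n] <- 3L * (nd[a] - 1L) + i
          jj[n] <- 3L * (nd[b] - 1L) + k
          xx[n] <- B[i, k]
        }
      }
    }
  }
  out <- list(res = res)
  if (want_jac) out$trip <- list(i = ii[1:n], j = jj[1:n], x = xx[1:n])
  out
}

activation_scale <- function(problem, t) {
  act <- problem$active
  tt <- (t - act$activation_onset) %% problem$cycle_period
  ct <- temporal_activation(tt, act)
  act$T_ref * ct * problem$act_multiplier
}

#' Assemble the stabilized mixed residual (and tangent)
#'
#' Full weak-form residual at a state: internal virtual work of
#' `P - p J F^-T`, incompressibility with pressure stabilization, Robin
#' surface term with backward-Euler velocity, and the follower cavity
#' pressure on every chamber endocardium.
#'
#' @param problem a [fem_problem()]
#' @param state a [mech_state()]
#' @param pressures named chamber pressures (kPa); every chamber in
#'   `mesh$endo_patches` must have an entry
#' @param want_jac also return the consistent tangent (sparse)
#' @param masks internal: Dirichlet mask/value list for in-place row
#'   substitution during Newton solves
#' @return list with `res` (length 4N), `jac` (if requested), `minJ`
#' @export
fem_residual <- function(problem, state, pressures = NULL, want_jac = TRUE,
                         masks = NULL) {
  mesh <- problem$mesh
  N <- nrow(mesh$vertices)
  chambers <- names(mesh$endo_patches)
  if (length(chambers)) {
    missing <- setdiff(chambers, names(pressures))
    if (length(missing))
      stop("no pressure supplied for chamber(s): ", paste(missing, collapse = ", "))
  }
  act <- activation_scale(problem, state$t)
  vol <- fem_assemble_volume(mesh$vertices, mesh$tets, state$u, state$p,
                             problem$triads, as_matpar(problem$passive),
                             as_actpar(problem$active), act, want_jac)
  if (vol$bad_el > 0)
    return(list(res = NULL, minJ = vol$minJ, bad_el = vol$bad_el, ok = FALSE))
  x <- c(state$u, state$p)
  x_prev <- c(state$u_prev, numeric(N))
  res <- vol$res +
    as.vector(problem$K_stab %*% x) +
    as.vector(problem$K_robin %*% x) +
    as.vector(problem$C_robin %*% (x - x_prev)) / state$dt
  trips <- if (want_jac)
    list(i = vol$i, j = vol$j, x = vol$x) else NULL
  verts_def <- mesh$vertices + matrix(state$u, ncol = 3, byrow = TRUE)
  for (ch in chambers) {
    P <- pressures[[ch]]
    tris <- mesh$surface_patches[[mesh$endo_patches[[ch]]]]
    fl <- follower_load(verts_def, tris, P, N, want_jac)
    res <- res + fl$res
    if (want_jac)
      trips <- list(i = c(trips$i, fl$trip$i), j = c(trips$j, fl$trip$j),
                    x = c(trips$x, fl$trip$x))
  }
  if (!is.null(masks))
    res <- masks$mask * res + (1 - masks$mask) * (x - masks$vals)
  out <- list(res = res, minJ = vol$minJ, ok = TRUE)
  if (want_jac) {
    ii <- c(trips$i, problem$Kc_T$i, problem$Cc_T$i)
    jj <- c(trips$j, problem$Kc_T$j, problem$Cc_T$j)
    xx <- c(trips$x, problem$Kc_T$x, problem$Cc_T$x / state$dt)
    if (!is.null(masks)) {
      keep <- masks$mask[ii] != 0
      fixed <- which(masks$mask == 0)
      ii <- c(ii[keep], fixed)
      jj <- c(jj[keep], fixed)
      xx <- c(xx[keep], rep(1, length(fixed)))
    }
    out$jac <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                    dims = c(4 * N, 4 * N))
    out
  } else out
}

#' Assemble the nodal residual vector
#'
#' Residual-only convenience wrapper around [fem_residual()].
#'
#' @inheritParams fem_residual
#' @param chamber_pressures named chamber pressures (kPa)
#' @return residual vector of length 4N (u dofs then p dofs)
#' @export
assemble_residual <- function(state, problem, chamber_pressures = NULL) {
  r <- fem_residual(problem, state, chamber_pressures, want_jac = FALSE)
  if (!r$ok) stop("inverted element (J <= 0) in element ", r$bad_el)
  r$res
}

dirichlet_masks <- function(problem) {
  N <- nrow(problem$mesh$vertices)
  ndof <- 4 * N
  mask <- rep(1, ndof)
  vals <- numeric(ndof)
  dc <- problem$dirichlet
  if (!is.null(dc) && nrow(dc)) {
    dofs <- 3L * (dc$node - 1L) + dc$comp
    mask[dofs] <- 0
    vals[dofs] <- dc$value
  }
  list(mask = mask, vals = vals)
}

#' Newton solve of the mechanics problem at fixed chamber pressures
#'
#' Full Newton iteration with the analytic consistent tangent and sparse LU
#' linear solves; Dirichlet constraints are enforced by row substitution.
#' On non-convergence the caller can sub-step the load (see
#' [solve_mech_pressures()]).
#'
#' @param problem a [fem_problem()]
#' @param state initial guess (a [mech_state()]); `u_prev`, `t`, `dt` are
#'   taken from it
#' @param pressures named chamber pressures (kPa)
#' @param rtol,atol relative/absolute residual tolerances
#' @param max_iter Newton iteration cap
#' @param full_newton reassemble and refactor the tangent every iteration
#'   (default); with `FALSE` the factorization is frozen while the residual
#'   contracts fast enough (modified Newton, used by the coupling driver
#'   where successive solves differ only slightly)
#' @return list with `state`, `converged`, `iterations`, `res_norms`
#' @export
newton_solve <- function(problem, state, pressures = NULL,
                         rtol = 1e-8, atol = 1e-10, max_iter = 25,
                         full_newton = TRUE) {
  dm <- dirichlet_masks(problem)
  x <- c(state$u, state$p)
  N <- nrow(problem$mesh$vertices)
  res_norms <- numeric(0)
  converged <- FALSE
  r0 <- NULL
  lu <- NULL
  for (it in seq_len(max_iter + 1L)) {
    st <- state; st$u <- x[1:(3 * N)]; st$p <- x[3 * N + 1:N]
    want_jac <- full_newton || is.null(lu) ||
      (length(res_norms) >= 2 &&
       res_norms[length(res_norms)] > 0.2 * res_norms[length(res_norms) - 1])
    rr <- fem_residual(problem, st, pressures, want_jac = want_jac, masks = dm)
    if (!rr$ok)
      return(list(state = st, converged = FALSE, iterations = it - 1L,
                  res_norms = res_norms, diverged = "inverted_element",
                  minJ = rr$minJ))
    res <- rr$res
    rn <- sqrt(sum(res^2))
    res_norms <- c(res_norms, rn)
    if (is.null(r0)) r0 <- rn
    if (rn <= max(atol, rtol * r0)) { converged <- TRUE; break }
    # roundoff-floor stagnation: residual far below any meaningful force
    # scale but no longer contracting (assembly floating-point floor)
    nr <- length(res_norms)
    if (nr >= 3 && rn < 1e-5 * r0 &&
        rn > 0.5 * res_norms[nr - 1] &&
        res_norms[nr - 1] > 0.5 * res_norms[nr - 2]) {
      converged <- TRUE
      break
    }
    if (it > max_iter) break
    if (want_jac)
      lu <- tryCatch(Matrix::lu(rr$jac), error = function(e) NULL)
    dx <- if (is.null(lu)) NULL else
      tryCatch(as.vector(Matrix::solve(lu, res)), error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx)))
      return(list(state = st, converged = FALSE, iterations = it,
                  res_norms = res_norms, diverged = "linear_solve"))
    x <- x - dx
    x[dm$mask == 0] <- dm$vals[dm$mask == 0]  # constraints hold exactly
  }
  st <- state; st$u <- x[1:(3 * N)]; st$p <- x[3 * N + 1:N]
  list(state = st, converged = converged, iterations = length(res_norms) - 1L,
       res_norms = res_norms)
}

#' Solve mechanics at target pressures with load continuation
#'
#' Wraps [newton_solve()]; if the Newton iteration fails at the target
#' chamber pressures, the pressure increment from `from_pressures` is halved
#' recursively (up to `max_depth` bisections).
#'
#' @param problem a [fem_problem()]
#' @param state initial guess / previous-step state
#' @param pressures target chamber pressures (kPa, named)
#' @param from_pressures pressures at which `state` is in equilibrium
#'   (default 0)
#' @param max_depth maximum continuation bisection depth
#' @param ... passed to [newton_solve()]
#' @return as [newton_solve()], plus `n_solves`
#' @export
solve_mech_pressures <- function(problem, state, pressures,
                                 from_pressures = NULL, max_depth = 6, ...) {
  chambers <- names(problem$mesh$endo_patches)
  if (is.null(from_pressures))
    from_pressures <- stats::setNames(numeric(length(chambers)), chambers)
  n_solves <- 0L
  recurse <- function(state, p_from, p_to, depth) {
    sol <- newton_solve(problem, state, p_to, ...)
    n_solves <<- n_solves + 1L
    if (sol$converged) return(sol)
    if (depth >= max_depth)
      return(sol)
    p_mid <- (p_from + p_to) / 2
    mid <- recurse(state, p_from, p_mid, depth + 1L)
    if (!mid$converged) return(mid)
    recurse(mid$state, p_mid, p_to, depth + 1L)
  }
  out <- recurse(state, from_pressures[chambers], pressures[chambers], 0L)
  out$n_solves <- n_solves
  out
}
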