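#' Configuration of a coupled multi-cycle simulation
#'
#' Declares which chambers are resolved with the 3D FE wall model (the
#' others run as elastance surrogates), the time discretization, the number
#' of cycles, per-chamber contractility multipliers, and all parameter
#' blocks.
#'
#' @param mesh a [labeled_mesh()] for the 3D chambers (NULL = all-surrogate)
#' @param fibers a [microstructure_field()] for the mesh
#' @param chambers_3d chamber names simulated in 3D (must be the chambers of
#'   `mesh$endo_patches`)
#' @param passive,active,robin,stab mechanics parameter blocks
#' @param dirichlet_patch patch held fixed (truncated-vessel rim role)
#' @param circulation [circ_params()]
#' @param elastances surrogate chamber parameters ([default_elastances()])
#' @param dt time step (ms); `cycle_period` must be a multiple
#' @param cycle_period cardiac cycle length (ms)
#' @param n_cycles maximum number of cycles
#' @param coupling_tol chamber volume residual tolerance (mL)
#' @param steady_tol_pct per-chamber end-diastolic volume change (%) between
#'   consecutive cycles declaring periodic steady state
#' @param contractility named per-chamber multipliers (ischemia protocol)
#' @param snapshot_every store a displacement snapshot every this many steps
#' @param seed seed for any jittered initial guess (optional)
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(mesh = NULL, fibers = NULL,
                              chambers_3d = character(),
                              passive = passive_params(),
                              active = active_params(),
                              robin = robin_params(),
                              stab = stab_params(),
                              dirichlet_patch = "base",
                              circulation = circ_params(),
                              elastances = default_elastances(),
                              dt = 1, cycle_period = 800, n_cycles = 10,
                              coupling_tol = 1e-4, steady_tol_pct = 0.5,
                              contractility = c(lv = 1, rv = 1, la = 1, ra = 1),
                              snapshot_every = 10, seed = NULL) {
  if (abs(cycle_period / dt - round(cycle_period / dt)) > 1e-9)
    stop("cycle_period must be a multiple of dt")
  if (any(contractility < 0)) stop("contractility multipliers must be >= 0")
  if (length(chambers_3d)) {
    stopifnot(!is.null(mesh), !is.null(fibers))
    if (!setequal(chambers_3d, names(mesh$endo_patches)))
      stop("chambers_3d must match the chambers of the mesh")
  }
  structure(list(mesh = mesh, fibers = fibers, chambers_3d = chambers_3d,
                 passive = passive, active = active, robin = robin,
                 stab = stab, dirichlet_patch = dirichlet_patch,
                 circulation = circulation, elastances = elastances,
                 dt = dt, cycle_period = cycle_period, n_cycles = n_cycles,
                 coupling_tol = coupling_tol, steady_tol_pct = steady_tol_pct,
                 contractility = contractility,
                 snapshot_every = snapshot_every, seed = seed),
            class = "simulation_config")
}

#' Scale a chamber's contractility (ischemia protocol)
#'
#' Multiplies the active tension generation of the named chamber: `T_ref`
#' for a 3D chamber's elements, the active elastance rise `E_max - E_min`
#' for a surrogate chamber.  All other parameters are unchanged.
#'
#' @param config a [simulation_config()]
#' @param chamber one of "lv", "rv", "la", "ra"
#' @param multiplier contractility multiplier in [0, 1]
#' @return the modified config
#' @export
apply_ischemia <- function(config, chamber, multiplier) {
  if (!chamber %in% c("lv", "rv", "la", "ra"))
    stop("unknown chamber '", chamber, "'")
  stopifnot(multiplier >= 0, multiplier <= 1)
  config$contractility[chamber] <- multiplier
  config
}

surrogate_pressures <- function(config, circ, t) {
  ch <- setdiff(c("lv", "rv", "la", "ra"), config$chambers_3d)
  out <- numeric(0)
  for (c1 in ch) {
    ep <- config$elastances[[c1]]
    m <- config$contractility[[c1]]
    if (!is.null(m) && m != 1) ep$E_max <- ep$E_min + m * (ep$E_max - ep$E_min)
    V <- switch(c1, lv = circ$V_lv, rv = circ$V_rv, la = circ$V_la, ra = circ$V_ra)
    out[c1] <- elastance_chamber_pressure(V, t, ep, config$cycle_period)
  }
  out
}

circ_chamber_volume <- function(circ, chamber) {
  switch(chamber, lv = circ$V_lv, rv = circ$V_rv, la = circ$V_la, ra = circ$V_ra)
}

# robust scalar coupling root: bracket the monotone residual R(P) by
# geometric expansion, then Illinois-modified regula falsi with bisection
# safeguard (the residual is kinked where valves open/close)
coupled_scalar_root <- function(eval_R, P0, out0, tol, slope0 = NULL,
                                corners = numeric(0), max_eval = 80) {
  nm <- names(P0)
  evals <- 0L
  ev <- function(P) { evals <<- evals + 1L; eval_R(stats::setNames(P, nm)) }
  P <- as.numeric(P0); out <- out0; R <- as.numeric(out0$R)
  if (abs(R) < tol)
    return(list(P = stats::setNames(P, nm), out = out,
                slope = if (is.null(slope0)) 1 else slope0))
  P_lo <- P_hi <- R_lo <- R_hi <- NULL
  if (R > 0) { P_hi <- P; R_hi <- R } else { P_lo <- P; R_lo <- R }
  # initial guess from the warm-started slope, then geometric expansion;
  # failed evaluations (unphysical trial pressures) shrink the step
  step <- if (!is.null(slope0) && is.finite(slope0) && slope0 > 1e-8)
    min(abs(R) / slope0 * 1.5, 60) else 2
  step <- max(step, 0.01)
  while (is.null(P_lo) || is.null(P_hi)) {
    if (evals > max_eval) return(NULL)
    P_try <- if (is.null(P_hi)) P_lo + step else P_hi - step
    o <- ev(P_try)
    if (is.null(o)) { step <- step / 2; if (step < 1e-8) return(NULL); next }
    Rt <- as.numeric(o$R)
    if (abs(Rt) < tol)
      return(list(P = stats::setNames(P_try, nm), out = o,
                  slope = abs((Rt - R) / (P_try - P)) + 1e-8))
    if (Rt > 0) { P_hi <- P_try; R_hi <- Rt } else { P_lo <- P_try; R_lo <- Rt }
    step <- step * 3
  }
  side <- 0L
  repeat {
    if (evals > max_eval) return(NULL)
    # try untested kink candidates inside the bracket first: once the kink
    # is isolated, the residual is near-linear on each side and the secant
    # finishes in one or two evaluations
    inside <- corners > P_lo + 1e-9 & corners < P_hi - 1e-9
    if (any(inside)) {
      P_sec <- corners[inside][which.max(pmin(corners[inside] - P_lo,
                                              P_hi - corners[inside]))]
      corners <- corners[corners != P_sec]
    } else {
      P_sec <- (P_lo * R_hi - P_hi * R_lo) / (R_hi - R_lo)
      w <- (P_sec - P_lo) / (P_hi - P_lo)
      if (!is.finite(P_sec) || w < 0.01 || w > 0.99) P_sec <- (P_lo + P_hi) / 2
    }
    o <- ev(P_sec)
    if (is.null(o)) return(NULL)
    Rt <- as.numeric(o$R)
    if (abs(Rt) < tol) {
      slope <- (R_hi - R_lo) / (P_hi - P_lo)
      return(list(P = stats::setNames(P_sec, nm), out = o,
                  slope = max(slope, 1e-8)))
    }
    if (Rt > 0) {
      if (side == 1L) R_lo <- R_lo / 2       # Illinois: deflate stale end
      P_hi <- P_sec; R_hi <- Rt; side <- 1L
    } else {
      if (side == -1L) R_hi <- R_hi / 2
      P_lo <- P_sec; R_lo <- Rt; side <- -1L
    }
  }
}

#' Advance the coupled 3D-0D system by one timestep
#'
#' Finds chamber pressures `P*` for the 3D chambers such that the FE cavity
#' volumes at `P*` equal the 0D chamber volumes after a circulation step
#' driven by `P*` (residual `R_ch = V_FE - V_circ`, quasi-Newton with a
#' finite-difference Jacobian, warm-started from the previous step's
#' pressures and Jacobian).  On stagnation the step is bisected in time.
#'
#' @param problem the [fem_problem()] of the 3D chambers
#' @param mech converged [mech_state()] at the previous time level
#' @param circ `circ_state` at the previous time level
#' @param t_new new time level (ms)
#' @param dt step (ms)
#' @param config [simulation_config()]
#' @param P_guess warm-start pressures (mmHg) for the 3D chambers
#' @param J_guess warm-start coupling Jacobian (or NULL)
#' @param depth internal bisection depth
#' @return list with `mech`, `circ`, `P` (mmHg), `resid` (mL), `n_fe`,
#'   `J` (coupling Jacobian for warm start), `converged`
#' @export
solve_coupled_timestep <- function(problem, mech, circ, t_new, dt, config,
                                   P_guess, J_guess = NULL, depth = 0L) {
  ch3 <- config$chambers_3d
  t_old <- t_new - dt
  cp_sur <- surrogate_pressures(config, circ, t_old)
  if (!length(ch3)) {
    circ2 <- circ_step(circ, cp_sur, dt, config$circulation)
    return(list(mech = mech, circ = circ2, P = P_guess, resid = 0,
                n_fe = 0L, J = J_guess, converged = TRUE))
  }
  n <- length(ch3)
  warm <- mech
  warm$t <- t_new; warm$dt <- dt; warm$u_prev <- mech$u
  env <- new.env()
  env$warm <- warm
  env$n_fe <- 0L
  eval_R <- function(P) {
    names(P) <- ch3
    sol <- newton_solve(problem, env$warm, P * KPA_PER_MMHG,
                        full_newton = FALSE)
    if (!sol$converged) {
      st0 <- mech; st0$t <- t_new; st0$dt <- dt; st0$u_prev <- mech$u
      sol <- solve_mech_pressures(problem, st0, P * KPA_PER_MMHG,
                                  from_pressures = P_guess * KPA_PER_MMHG)
    }
    if (!sol$converged) return(NULL)
    env$warm <- sol$state
    env$n_fe <- env$n_fe + 1L
    cp <- c(cp_sur, P)
    circ2 <- tryCatch(circ_step(circ, cp, dt, config$circulation),
                      error = function(e) NULL)
    if (is.null(circ2)) return(NULL)   # unphysical trial pressure
    V_fe <- vapply(ch3, function(c1) cavity_volume(problem$mesh, c1, sol$state$u), 0)
    list(R = V_fe - vapply(ch3, function(c1) circ_chamber_volume(circ2, c1), 0),
         circ = circ2, state = sol$state)
  }
  P <- P_guess
  out <- eval_R(P)
  fail <- is.null(out)
  J <- J_guess
  if (!fail && n == 1L) {
    # scalar root: R(P) is monotone increasing but kinked at valve
    # open/close corners, so use a bracketed secant with bisection fallback
    # candidate kink locations of R(P): the neighboring chamber/vascular
    # pressures where a valve of this chamber opens or closes
    pars <- config$circulation
    corners <- c(cp_sur,
                 sa = (circ$V_sa - pars$V0_sa) / pars$C_sa,
                 pa = (circ$V_pa - pars$V0_pa) / pars$C_pa)
    root <- coupled_scalar_root(eval_R, P, out, config$coupling_tol,
                                slope0 = if (!is.null(J)) J[1, 1],
                                corners = as.numeric(corners))
    if (is.null(root)) {
      fail <- TRUE
    } else {
      P <- root$P; out <- root$out
      J <- matrix(root$slope, 1, 1)
    }
  } else if (!fail) {
    if (is.null(J)) {
      # finite-difference Jacobian, 1e-3 mmHg perturbation
      J <- matrix(0, n, n)
      for (k in seq_len(n)) {
        Pk <- P; Pk[k] <- Pk[k] + 1e-3
        ok <- eval_R(Pk)
        if (is.null(ok)) { fail <- TRUE; break }
        J[, k] <- (ok$R - out$R) / 1e-3
      }
    }
  }
  if (!fail) {
    it <- 0L
    while (sqrt(sum(out$R^2)) >= config$coupling_tol) {
      it <- it + 1L
      if (it > 40L) { fail <- TRUE; break }
      dP <- tryCatch(solve(J, out$R), error = function(e) NULL)
      if (is.null(dP) || any(!is.finite(dP))) { fail <- TRUE; break }
      # step limiting for robustness of the diode nonlinearity
      dP <- pmin(pmax(-dP, -25), 25)
      P_new <- P + dP
      out_new <- eval_R(P_new)
      if (is.null(out_new)) { fail <- TRUE; break }
      # Broyden update
      dR <- out_new$R - out$R
      s <- P_new - P
      J <- J + outer(as.vector(dR - J %*% s), s) / sum(s^2)
      P <- P_new; out <- out_new
      if (it %% 15L == 0L) {
        # refresh Jacobian on slow progress
        for (k in seq_len(n)) {
          Pk <- P; Pk[k] <- Pk[k] + 1e-3
          ok <- eval_R(Pk)
          if (is.null(ok)) { fail <- TRUE; break }
          J[, k] <- (ok$R - out$R) / 1e-3
        }
        if (fail) break
      }
    }
  }
  if (fail) {
    if (depth >= 3L)
      stop("coupled timestep failed to converge at t = ", t_new,
           " ms after dt bisection")
    half <- solve_coupled_timestep(problem, mech, circ, t_new - dt / 2, dt / 2,
                                   config, P_guess, NULL, depth + 1L)
    return(solve_coupled_timestep(problem, half$mech, half$circ, t_new, dt / 2,
                                  config, half$P, half$J, depth + 1L))
  }
  # the 0D state keeps its own (exactly conservative) chamber volumes; the
  # root finder has enforced |V_FE - V_circ| < tol so no overwrite is needed
  list(mech = out$state, circ = out$circ, P = P, resid = sqrt(sum(out$R^2)),
       n_fe = env$n_fe, J = J, converged = TRUE)
}

#' Run the coupled system over multiple cardiac cycles
#'
#' Advances the bidirectionally coupled 3D-0D system cycle by cycle until a
#' time-periodic steady state (per-chamber end-diastolic volume change below
#' `steady_tol_pct` between consecutive cycles) or `n_cycles`.  With no 3D
#' chambers the driver reduces exactly to the pure 0D loop.
#'
#' @param config a [simulation_config()]
#' @return object of class `coupled_run`: `record` (full [beat_record()]),
#'   `final_cycle`, `snapshots` (displacements, 3D runs), `coupling`
#'   (per-step residual norms), `steady`, `edv_history`, `problem`
#' @export
run_cardiac_cycles <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  ch3 <- config$chambers_3d
  problem <- NULL
  mech <- NULL
  if (length(ch3)) {
    mult <- config$contractility[[ch3[1]]]
    problem <- fem_problem(config$mesh, config$fibers, config$passive,
                           config$active, config$robin, "epi",
                           stab = config$stab,
                           act_multiplier = mult,
                           cycle_period = config$cycle_period)
    problem <- apply_dirichlet(problem, config$dirichlet_patch)
    mech <- mech_state(config$mesh, t = 0, dt = config$dt)
  }
  circ <- circ_state_init(config$circulation)
  # initialize 3D chamber volumes from the reference cavity
  for (c1 in ch3) {
    v <- cavity_volume(config$mesh, c1)
    switch(c1, lv = { circ$V_lv <- v }, rv = { circ$V_rv <- v },
           la = { circ$V_la <- v }, ra = { circ$V_ra <- v })
  }
  steps <- round(config$cycle_period / config$dt)
  nts <- config$n_cycles * steps
  rec <- beat_record_alloc(nts)
  resids <- numeric(nts)
  snap_t <- numeric(0); snap_u <- list()
  P_prev <- stats::setNames(rep(2, length(ch3)), ch3)
  J_prev <- NULL
  edv_hist <- NULL
  steady <- FALSE
  n_done <- 0L
  for (ic in seq_len(config$n_cycles)) {
    for (is in seq_len(steps)) {
      i <- (ic - 1L) * steps + is
      t_new <- i * config$dt
      step <- solve_coupled_timestep(problem, mech, circ, t_new, config$dt,
                                     config, P_prev, J_prev)
      mech <- step$mech; circ <- step$circ
      P_prev <- step$P; J_prev <- step$J
      resids[i] <- step$resid
      rec <- beat_record_push(rec, i, circ)
      if (length(ch3) && (is %% config$snapshot_every == 0L)) {
        snap_t <- c(snap_t, t_new)
        snap_u[[length(snap_u) + 1L]] <- mech$u
      }
      n_done <- i
    }
    edv <- apply(rec$volume[((ic - 1L) * steps + 1L):(ic * steps), , drop = FALSE],
                 2, max)
    edv_hist <- rbind(edv_hist, edv)
    if (ic > 1) {
      rel <- abs(edv - edv_hist[ic - 1L, ]) / pmax(edv_hist[ic - 1L, ], 1e-9)
      if (all(rel < config$steady_tol_pct / 100)) { steady <- TRUE; break }
    }
  }
  rec <- lapply(rec, function(m) if (is.matrix(m)) m[seq_len(n_done), , drop = FALSE] else m)
  rec <- beat_record_finalize(rec, config$dt)
  if (!steady)
    warning("coupled run did not reach a periodic steady state within ",
            config$n_cycles, " cycles; returning the partial record")
  structure(list(record = rec,
                 final_cycle = last_cycle(rec, config$cycle_period),
                 snapshots = list(times = snap_t, u = snap_u),
                 coupling = resids[seq_len(n_done)],
                 steady = steady, edv_history = edv_hist,
                 final_circ = circ, final_mech = mech,
                 problem = problem, config = config),
            class = "coupled_run")
}

#' @export
print.coupled_run <- function(x, ...) {
  cat("coupled_run:", length(x$record$time), "steps,",
      if (x$steady) "steady-periodic\n" else "not yet periodic\n")
  if (length(x$coupling))
    cat(sprintf("  max coupling residual %.2e mL\n", max(x$coupling)))
  print(x$final_cycle)
  invisible(x)
}
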