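#' Closed-loop lumped-parameter circulation parameters
#'
#' Four vascular compartments (systemic arteries/veins, pulmonary
#' arteries/veins), each a linear compliance `P = (V - V_unstressed)/C` with
#' a series outflow resistance, and four ideal-diode valves (mitral, aortic,
#' tricuspid, pulmonic) with open resistances.  Loop topology:
#' LA -mitral-> LV -aortic-> SysArt -> SysVein -> RA -tricuspid-> RV
#' -pulmonic-> PulmArt -> PulmVein -> LA.  Vein-to-atrium segments carry no
#' valves (flow may transiently reverse).
#'
#' There is no authoritative parameter table for this particular loop; the
#' defaults below were calibrated once on the elastance
#' surrogate configuration to give roughly physiologic adult hemodynamics
#' (LV ~120/8 mmHg, stroke volume ~70 mL at a 800 ms cycle) and are plain
#' configuration entries.
#'
#' Units: compliance mL/mmHg, resistance mmHg*ms/mL, volume mL.
#'
#' @param C_sa,C_sv,C_pa,C_pv compartment compliances
#' @param V0_sa,V0_sv,V0_pa,V0_pv unstressed volumes
#' @param R_sa,R_sv,R_pa,R_pv compartment outflow resistances (systemic
#'   arterial = systemic vascular resistance, etc.)
#' @param R_mv,R_av,R_tv,R_pvalve open valve resistances
#' @param total_volume total blood volume in the loop (mL)
#' @param dt_max_internal internal substep cap (ms) for [circ_step()]
#' @return object of class `circ_params`
#' @export
circ_params <- function(C_sa = 1.6, C_sv = 40, C_pa = 4.5, C_pv = 12,
                        V0_sa = 450, V0_sv = 2400, V0_pa = 60, V0_pv = 350,
                        R_sa = 1050, R_sv = 45, R_pa = 90, R_pv = 18,
                        R_mv = 4, R_av = 6, R_tv = 3, R_pvalve = 5,
                        total_volume = 4250, dt_max_internal = 1) {
  p <- list(C_sa = C_sa, C_sv = C_sv, C_pa = C_pa, C_pv = C_pv,
            V0_sa = V0_sa, V0_sv = V0_sv, V0_pa = V0_pa, V0_pv = V0_pv,
            R_sa = R_sa, R_sv = R_sv, R_pa = R_pa, R_pv = R_pv,
            R_mv = R_mv, R_av = R_av, R_tv = R_tv, R_pvalve = R_pvalve,
            total_volume = total_volume, dt_max_internal = dt_max_internal)
  stopifnot(all(unlist(p[1:16]) > 0))
  if (total_volume <= V0_sa + V0_sv + V0_pa + V0_pv)
    stop("total blood volume must exceed the summed unstressed volumes")
  structure(p, class = "circ_params")
}

#' Time-varying elastance surrogate chamber parameters
#'
#' 0D chamber model `P = [E_min + (E_max - E_min) C_t(t)] (V - V0)`, floored
#' at 0 below `V0`, sharing the temporal activation shape of the 3D active
#' stress law.
#'
#' @param E_max,E_min peak/baseline elastance (mmHg/mL)
#' @param V0 zero-pressure volume (mL)
#' @param activation [active_params()] supplying `t0`, `t_t`, `tau` and
#'   `activation_onset` for the activation waveform
#' @return object of class `elastance_params`
#' @export
elastance_params <- function(E_max = 2.6, E_min = 0.08, V0 = 10,
                             activation = active_params()) {
  stopifnot(E_max >= E_min, E_min > 0)
  structure(list(E_max = E_max, E_min = E_min, V0 = V0,
                 activation = activation),
            class = "elastance_params")
}

#' Default elastance surrogate set for the four chambers
#'
#' Ventricles activate at cycle start with the reference temporal activation
#' timing; atria activate in late diastole (720 ms of the 800 ms cycle) with
#' a shorter twitch.
#'
#' @return named list of [elastance_params()] for lv, rv, la, ra
#' @export
default_elastances <- function() {
  vent_act <- active_params()                      # t0 275, t_t 300, tau 25
  atr_act <- active_params(t0 = 90, t_t = 110, tau = 20, activation_onset = 720)
  list(
    lv = elastance_params(E_max = 2.6, E_min = 0.08, V0 = 10, activation = vent_act),
    rv = elastance_params(E_max = 0.6, E_min = 0.045, V0 = 15, activation = vent_act),
    la = elastance_params(E_max = 0.45, E_min = 0.16, V0 = 5, activation = atr_act),
    ra = elastance_params(E_max = 0.38, E_min = 0.14, V0 = 5, activation = atr_act))
}

#' Elastance chamber pressure
#'
#' @param V chamber volume (mL)
#' @param t time within the cycle (ms)
#' @param params [elastance_params()]
#' @param cycle_period cycle length (ms) for wrapping the activation time
#' @return pressure (mmHg), floored at 0 for `V < V0`
#' @export
elastance_chamber_pressure <- function(V, t, params, cycle_period = 800) {
  stopifnot(V >= 0)
  act <- params$activation
  tt <- (t - act$activation_onset) %% cycle_period
  ct <- temporal_activation(tt, act)
  E <- params$E_min + (params$E_max - params$E_min) * ct
  max(E * (V - params$V0), 0)
}

#' Initial circulation state
#'
#' Distributes the total blood volume over compartments and chambers in
#' physiologic proportions; the loop settles to its own periodic state
#' within a few simulated cycles regardless of the exact split.
#'
#' @param params [circ_params()]
#' @param chamber_volumes optional named initial chamber volumes (mL)
#' @return object of class `circ_state`: vascular volumes `V_sa, V_sv,
#'   V_pa, V_pv`, chamber volumes `V_lv, V_rv, V_la, V_ra`, chamber
#'   pressures `P` (mmHg), valve/segment flows `Q` (mL/ms), time `t`
#' @export
circ_state_init <- function(params = circ_params(), chamber_volumes = NULL) {
  ch <- list(lv = 130, rv = 120, la = 60, ra = 60)
  if (!is.null(chamber_volumes)) ch[names(chamber_volumes)] <- chamber_volumes
  stressed <- params$total_volume - sum(unlist(ch)) -
    (params$V0_sa + params$V0_sv + params$V0_pa + params$V0_pv)
  if (stressed <= 0) stop("total volume too small for the requested chambers")
  # initial stressed-volume split ~ arterial/venous operating pressures
  w <- c(sa = 0.35, sv = 0.40, pa = 0.10, pv = 0.15)
  structure(list(
    V_sa = params$V0_sa + stressed * w[["sa"]],
    V_sv = params$V0_sv + stressed * w[["sv"]],
    V_pa = params$V0_pa + stressed * w[["pa"]],
    V_pv = params$V0_pv + stressed * w[["pv"]],
    V_lv = ch$lv, V_rv = ch$rv, V_la = ch$la, V_ra = ch$ra,
    P = c(lv = 0, rv = 0, la = 0, ra = 0),
    Q = c(mv = 0, av = 0, sys = 0, sv_ra = 0, tv = 0, pvalve = 0,
          pul = 0, pv_la = 0),
    t = 0), class = "circ_state")
}

#' Total blood volume of a circulation state
#' @param state a `circ_state`
#' @return total volume (mL)
#' @export
circ_total_volume <- function(state) {
  state$V_sa + state$V_sv + state$V_pa + state$V_pv +
    state$V_lv + state$V_rv + state$V_la + state$V_ra
}

#' Advance the closed-loop circulation by one step
#'
#' Vascular pressures follow the linear compliances, valves are ideal diodes
#' `Q = max(dP, 0)/R`, vein-to-atrium segments are plain resistances, and
#' volumes advance by explicit Euler volume updates (internally substepped
#' to at most `dt_max_internal`).  The four chamber pressures are inputs and
#' are held fixed over the step: for 3D chambers they are the root-found
#' coupling pressures at the new time level, which is the semi-implicit
#' element of the scheme.  Total volume is conserved exactly by
#' construction.
#'
#' @param state a `circ_state`
#' @param chamber_pressures named numeric (mmHg) for lv, rv, la, ra
#' @param dt step (ms)
#' @param params [circ_params()]
#' @return advanced `circ_state` (with updated flows and chamber pressures)
#' @export
circ_step <- function(state, chamber_pressures, dt, params = circ_params()) {
  stopifnot(dt > 0, all(is.finite(unlist(chamber_pressures))))
  cp <- chamber_pressures
  n_sub <- max(1L, ceiling(dt / params$dt_max_internal))
  h <- dt / n_sub
  s <- state
  for (k in seq_len(n_sub)) {
    P_sa <- (s$V_sa - params$V0_sa) / params$C_sa
    P_sv <- (s$V_sv - params$V0_sv) / params$C_sv
    P_pa <- (s$V_pa - params$V0_pa) / params$C_pa
    P_pv <- (s$V_pv - params$V0_pv) / params$C_pv
    Q <- c(
      mv = max(cp[["la"]] - cp[["lv"]], 0) / params$R_mv,
      av = max(cp[["lv"]] - P_sa, 0) / params$R_av,
      sys = (P_sa - P_sv) / params$R_sa,
      sv_ra = (P_sv - cp[["ra"]]) / params$R_sv,
      tv = max(cp[["ra"]] - cp[["rv"]], 0) / params$R_tv,
      pvalve = max(cp[["rv"]] - P_pa, 0) / params$R_pvalve,
      pul = (P_pa - P_pv) / params$R_pa,
      pv_la = (P_pv - cp[["la"]]) / params$R_pv)
    V_new <- c(
      lv = s$V_lv + h * (Q[["mv"]] - Q[["av"]]),
      sa = s$V_sa + h * (Q[["av"]] - Q[["sys"]]),
      sv = s$V_sv + h * (Q[["sys"]] - Q[["sv_ra"]]),
      ra = s$V_ra + h * (Q[["sv_ra"]] - Q[["tv"]]),
      rv = s$V_rv + h * (Q[["tv"]] - Q[["pvalve"]]),
      pa = s$V_pa + h * (Q[["pvalve"]] - Q[["pul"]]),
      pv = s$V_pv + h * (Q[["pul"]] - Q[["pv_la"]]),
      la = s$V_la + h * (Q[["pv_la"]] - Q[["mv"]]))
    if (any(V_new < 0))
      stop("negative compartment volume in circ_step; reduce dt")
    s$V_lv <- V_new[["lv"]]; s$V_sa <- V_new[["sa"]]
    s$V_sv <- V_new[["sv"]]; s$V_ra <- V_new[["ra"]]
    s$V_rv <- V_new[["rv"]]; s$V_pa <- V_new[["pa"]]
    s$V_pv <- V_new[["pv"]]; s$V_la <- V_new[["la"]]
    s$Q <- Q
  }
  s$P <- c(lv = cp[["lv"]], rv = cp[["rv"]], la = cp[["la"]], ra = cp[["ra"]])
  s$t <- state$t + dt
  s
}

#' Run the circulation with all four chambers as elastance surrogates
#'
#' Pure-0D closed-loop run used as a test harness and as the regression
#' reference for the coupled driver in the all-surrogate configuration.
#'
#' @param params [circ_params()]
#' @param elastances named list of [elastance_params()] (lv, rv, la, ra)
#' @param cycles number of cardiac cycles
#' @param dt step (ms)
#' @param cycle_period cycle length (ms)
#' @param init optional initial `circ_state`
#' @param steady_tol cycle-to-cycle max volume change (mL) declaring a
#'   periodic steady state
#' @return a [beat_record()] of all cycles with attributes
#'   `steady` (logical), `cycle_drift` (mL per cycle)
#' @export
run_0d_only <- function(params = circ_params(), elastances = default_elastances(),
                        cycles = 10, dt = 1, cycle_period = 800,
                        init = NULL, steady_tol = 0.1) {
  state <- if (is.null(init)) circ_state_init(params) else init
  steps <- round(cycle_period / dt)
  nts <- cycles * steps
  rec <- beat_record_alloc(nts)
  prev_cycle_vols <- NULL
  drift <- NA_real_
  steady <- FALSE
  for (ic in seq_len(cycles)) {
    for (is in seq_len(steps)) {
      tcyc <- ((ic - 1) * steps + is - 1) * dt
      cp <- c(
        lv = elastance_chamber_pressure(state$V_lv, tcyc, elastances$lv, cycle_period),
        rv = elastance_chamber_pressure(state$V_rv, tcyc, elastances$rv, cycle_period),
        la = elastance_chamber_pressure(state$V_la, tcyc, elastances$la, cycle_period),
        ra = elastance_chamber_pressure(state$V_ra, tcyc, elastances$ra, cycle_period))
      state <- circ_step(state, cp, dt, params)
      rec <- beat_record_push(rec, (ic - 1) * steps + is, state)
    }
    vols <- c(state$V_sa, state$V_sv, state$V_pa, state$V_pv,
              state$V_lv, state$V_rv, state$V_la, state$V_ra)
    if (!is.null(prev_cycle_vols)) {
      drift <- max(abs(vols - prev_cycle_vols))
      if (drift < steady_tol) { steady <- TRUE }
    }
    prev_cycle_vols <- vols
  }
  rec <- beat_record_finalize(rec, dt)
  if (!steady)
    warning("0D loop not yet periodic after ", cycles,
            " cycles (max cycle-to-cycle volume change ",
            format(drift, digits = 3), " mL)")
  attr(rec, "steady") <- steady
  attr(rec, "cycle_drift") <- drift
  attr(rec, "final_state") <- state
  rec
}
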