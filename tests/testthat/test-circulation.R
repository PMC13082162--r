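test_that("closed-loop step conserves blood volume exactly", {
  pars <- circ_params()
  st <- circ_state_init(pars)
  V0 <- circ_total_volume(st)
  set.seed(31)
  for (k in 1:50) {
    cp <- c(lv = runif(1, 0, 120), rv = runif(1, 0, 30),
            la = runif(1, 0, 20), ra = runif(1, 0, 12))
    st <- circ_step(st, cp, dt = 1, pars)
    expect_equal(circ_total_volume(st), V0, tolerance = 1e-12)
  }
  expect_true(all(unlist(st[c("V_sa", "V_sv", "V_pa", "V_pv",
                              "V_lv", "V_rv", "V_la", "V_ra")]) >= 0))
})

test_that("valves are ideal diodes and equal pressures give a stationary state", {
  pars <- circ_params()
  st <- circ_state_init(pars)
  # downstream above upstream -> zero valve flow
  st2 <- circ_step(st, c(lv = 5, rv = 5, la = 1, ra = 1), 1, pars)
  expect_identical(unname(st2$Q[["mv"]]), 0)   # P_la < P_lv
  expect_identical(unname(st2$Q[["tv"]]), 0)
  P_sa <- (st$V_sa - pars$V0_sa) / pars$C_sa
  expect_identical(unname(circ_step(st, c(lv = P_sa - 10, rv = 1, la = 1, ra = 1),
                                    1, pars)$Q[["av"]]), 0)
  # uniform pressure P everywhere: stationary equilibrium
  P <- 7
  st$V_sa <- pars$V0_sa + pars$C_sa * P
  st$V_sv <- pars$V0_sv + pars$C_sv * P
  st$V_pa <- pars$V0_pa + pars$C_pa * P
  st$V_pv <- pars$V0_pv + pars$C_pv * P
  st3 <- circ_step(st, c(lv = P, rv = P, la = P, ra = P), 5, pars)
  expect_equal(unname(st3$Q), rep(0, 8))
  expect_equal(st3$V_lv, st$V_lv)
  expect_equal(st3$V_sa, st$V_sa)
})

test_that("elastance surrogate pressure is linear in elastance and floored", {
  ep <- elastance_params(E_max = 2, E_min = 0.1, V0 = 10)
  expect_identical(elastance_chamber_pressure(10, 100, ep), 0)
  expect_identical(elastance_chamber_pressure(4, 100, ep), 0)  # below V0
  # no activation: baseline elastance
  expect_equal(elastance_chamber_pressure(60, 0, ep), 0.1 * 50)
  # peak activation time: doubling E_max doubles isovolumic peak pressure
  tpk <- ep$activation$t0
  p1 <- elastance_chamber_pressure(60, tpk, ep)
  ep2 <- elastance_params(E_max = 4, E_min = 0.1, V0 = 10)
  expect_equal(elastance_chamber_pressure(60, tpk, ep2) / p1,
               4 / 2, tolerance = 1e-9)
})

test_that("pure 0D loop reaches a conservative periodic steady state", {
  rec <- run_0d_only(cycles = 12)
  expect_true(attr(rec, "steady"))
  fc <- last_cycle(rec)
  dt <- fc$time[2] - fc$time[1]
  m <- pv_metrics(fc, "lv")
  # flow-integral consistency: stroke volume equals aortic forward volume
  expect_equal(sum(fc$flow[, "av"]) * dt, m$SV, tolerance = 0.02 * m$SV)
  # conservation across the whole record
  tot <- rowSums(cbind(rec$volume, rec$vascular))
  expect_lt(max(abs(tot - tot[1])), 1e-9 * tot[1])
  # physiologic ballpark of the calibrated defaults
  expect_gt(m$EF, 45); expect_lt(m$EF, 70)
  expect_gt(m$peakP, 100); expect_lt(m$peakP, 145)
})

test_that("removing contractility makes the loop decay toward rest", {
  el <- default_elastances()
  for (ch in names(el)) el[[ch]]$E_max <- el[[ch]]$E_min  # constant elastance
  rec <- suppressWarnings(run_0d_only(elastances = el, cycles = 8))
  n <- length(rec$time)
  steps <- 800
  q_first <- max(abs(rec$flow[1:steps, ]))
  q_last <- max(abs(rec$flow[(n - steps + 1):n, ]))
  expect_lt(q_last, 0.05 * q_first)
})

test_that("unphysical circulation parameters are rejected", {
  expect_error(circ_params(C_sa = -1))
  expect_error(circ_params(total_volume = 100), "unstressed")
  expect_error(circ_step(circ_state_init(), c(lv = NaN, rv = 1, la = 1, ra = 1), 1),
               "finite")
})
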