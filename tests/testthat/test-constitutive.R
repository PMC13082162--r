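test_that("strain energy reproduces direct scalar evaluation of the law", {
  pp <- passive_params()
  # independent scalar oracle: Q and W computed literally
  E <- matrix(0, 3, 3); E[1, 1] <- 0.1
  Q <- pp$b_ff * 0.1^2
  expect_equal(strain_energy(E, params = pp), 0.5 * pp$C * (exp(Q) - 1),
               tolerance = 1e-12)
  expect_equal(strain_energy(E, params = pp), 21.8678, tolerance = 1e-4)
  # zero strain
  expect_identical(strain_energy(matrix(0, 3, 3)), 0)
  # symmetry of the law under sheet <-> sheet-normal swap
  E1 <- matrix(0, 3, 3); E1[2, 2] <- 0.05; E1[1, 3] <- E1[3, 1] <- 0.02
  E2 <- matrix(0, 3, 3); E2[3, 3] <- 0.05; E2[1, 2] <- E2[2, 1] <- 0.02
  expect_equal(strain_energy(E1), strain_energy(E2), tolerance = 1e-12)
  # general random case against the literal formula in the fiber frame
  set.seed(11)
  A <- matrix(rnorm(9, sd = 0.05), 3, 3); E <- (A + t(A)) / 2
  b <- matrix(c(pp$b_ff, pp$b_fx, pp$b_fx,
                pp$b_fx, pp$b_xx, pp$b_xx,
                pp$b_fx, pp$b_xx, pp$b_xx), 3, 3, byrow = TRUE)
  expect_equal(strain_energy(E),
               0.5 * pp$C * (exp(sum(b * E^2)) - 1), tolerance = 1e-12)
  # overflow guard
  expect_error(strain_energy(diag(3) * 10), "overflow")
})

test_that("passive stress is analytic derivative of the energy", {
  set.seed(12)
  Fm <- diag(3) + matrix(rnorm(9, sd = 0.02), 3, 3)
  pk <- passive_first_pk(Fm)
  h <- 1e-6
  Pfd <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- Fm; Fp[i, j] <- Fp[i, j] + h
    Fm2 <- Fm; Fm2[i, j] <- Fm2[i, j] - h
    Pfd[i, j] <- (strain_energy((t(Fp) %*% Fp - diag(3)) / 2) -
                  strain_energy((t(Fm2) %*% Fm2 - diag(3)) / 2)) / (2 * h)
  }
  expect_lt(max(abs(pk$P - Pfd)) / max(abs(Pfd)), 1e-6)
})

test_that("passive stress is frame-indifferent and vanishes at rest", {
  expect_equal(passive_first_pk(diag(3))$P, matrix(0, 3, 3), tolerance = 1e-14)
  # rigid rotation -> zero stress
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  expect_lt(max(abs(passive_first_pk(Rz)$P)), 1e-10)
  # P(QF) = Q P(F)
  set.seed(13)
  Fm <- diag(3) + matrix(rnorm(9, sd = 0.05), 3, 3)
  expect_equal(passive_first_pk(Rz %*% Fm)$P, Rz %*% passive_first_pk(Fm)$P,
               tolerance = 1e-10)
  expect_equal(strain_energy(kinematics_point(Rz %*% Fm)$E),
               strain_energy(kinematics_point(Fm)$E), tolerance = 1e-10)
  expect_error(passive_first_pk(-diag(3)), "inverted")
})

test_that("temporal activation matches the two-branch waveform", {
  ap <- active_params()
  expect_identical(temporal_activation(0, ap), 0)
  expect_equal(temporal_activation(275, ap), 1, tolerance = 1e-14)
  # value at relaxation onset, literal evaluation
  ct_tt <- 0.5 * (1 - cos(pi * 300 / 275))
  expect_equal(temporal_activation(300, ap), ct_tt, tolerance = 1e-12)
  expect_equal(temporal_activation(300, ap), 0.9797, tolerance = 1e-4)
  # branch continuity for arbitrary t_t, t0
  set.seed(14)
  for (k in 1:10) {
    ap2 <- active_params(t0 = runif(1, 50, 400), t_t = runif(1, 10, 500),
                         tau = runif(1, 5, 80))
    eps <- 1e-9
    expect_equal(temporal_activation(ap2$t_t - eps, ap2),
                 temporal_activation(ap2$t_t + eps, ap2), tolerance = 1e-6)
  }
  # bounds on a dense grid
  ct <- temporal_activation(seq(-50, 1200, by = 0.5), ap)
  expect_true(all(ct >= 0 & ct <= 1))
})

test_that("length-dependent gate has the analytic half-activation point", {
  ap <- active_params()
  # algebraic inversion: gate = 1/2 where ECa50 = Ca0; with Ca0 = Ca0_max
  # that is l = l0 + ln(2)/B
  l_half <- ap$l0 + log(2) / ap$B
  expect_equal(l_half, 1.7259, tolerance = 1e-4)
  expect_equal(length_dependent_gate(l_half, ap), 0.5, tolerance = 1e-12)
  # zero at/below resting length
  expect_identical(length_dependent_gate(c(ap$l0, ap$l0 - 0.1, 0.5), ap),
                   c(0, 0, 0))
  expect_lt(length_dependent_gate(ap$l0 + 1e-9, ap), 1e-8)
  # strictly increasing above l0, bounded by 1
  g <- length_dependent_gate(seq(ap$l0 + 1e-4, 3, length.out = 400), ap)
  expect_true(all(diff(g) > 0))
  expect_true(all(g > 0 & g < 1))
})

test_that("active stress is a fiber dyad with the prescribed magnitude", {
  ap <- active_params()
  # no activation -> zero tensor
  a0 <- active_first_pk(diag(3), t = 0)
  expect_equal(a0$P, matrix(0, 3, 3), tolerance = 1e-14)
  # F = I, l_ref at the half-activation length, t = t0: magnitude
  # T_ref * 0.5 * 1.0 along the fiber dyad
  ap2 <- active_params(l_ref = ap$l0 + log(2) / ap$B)
  a1 <- active_first_pk(diag(3), t = ap2$t0, params = ap2)
  expect_equal(a1$P, diag(c(1, 0, 0)) * ap2$T_ref * 0.5, tolerance = 1e-9)
  expect_equal(a1$gate, 0.5, tolerance = 1e-12)
  # bounded by T_ref for random stretches and times
  set.seed(15)
  for (k in 1:20) {
    Fm <- diag(3) + matrix(rnorm(9, sd = 0.1), 3, 3)
    if (det(Fm) <= 0) next
    a <- active_first_pk(Fm, t = runif(1, 0, 800))
    # unit dyad times T_ref * gate * C_t, all factors <= 1 beyond T_ref
    expect_lte(norm(a$P, "F"), ap$T_ref + 1e-9)
  }
  # active part also frame-indifferent: P_act(QF) = Q P_act(F)
  th <- 0.5
  Q <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3,
              byrow = TRUE)
  Fm <- diag(c(1.1, 0.95, 0.97))
  expect_equal(active_first_pk(Q %*% Fm, 150)$P,
               Q %*% active_first_pk(Fm, 150)$P, tolerance = 1e-10)
})
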