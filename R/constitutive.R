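#' Fung-type strain energy at a material point
#'
#' Evaluates \eqn{W = \tfrac{C}{2}(e^Q - 1)} with the anisotropy exponent Q
#' built from the Green--Lagrange strain expressed in the local
#' fiber/sheet/sheet-normal triad (see [passive_params()]).
#'
#' @param E symmetric 3x3 Green--Lagrange strain tensor (global frame)
#' @param triad 3x3 matrix whose rows are the unit vectors e_f0, e_s0, e_n0
#' @param params [passive_params()]
#' @return strain energy density (kPa)
#' @export
strain_energy <- function(E, triad = diag(3), params = passive_params()) {
  stopifnot(is.matrix(E), all(dim(E) == c(3, 3)))
  if (max(abs(E - t(E))) > 1e-10) stop("E must be symmetric")
  Eh <- triad %*% E %*% t(triad)
  b <- matrix(params$b_xx, 3, 3)
  b[1, 1] <- params$b_ff
  b[1, 2] <- b[2, 1] <- b[1, 3] <- b[3, 1] <- params$b_fx
  Q <- sum(b * Eh^2)
  if (Q > 250) stop("strain-energy exponent overflow: Q = ", format(Q))
  0.5 * params$C * expm1(Q)
}

#' Passive first Piola-Kirchhoff stress
#'
#' Analytic \eqn{P = F S} with \eqn{S = \partial W/\partial E} the second
#' Piola--Kirchhoff pullback of the Fung-type law.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`
#' @inheritParams strain_energy
#' @return list with `P` (first PK, kPa), `S` (second PK, kPa), `W`, `J`
#' @export
passive_first_pk <- function(F, triad = diag(3), params = passive_params()) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  if (det(F) <= 0) stop("inverted element: det(F) <= 0")
  cpp_fung_point(F, triad, as_matpar(params))
}

#' Temporal activation waveform C_t(t)
#'
#' \deqn{C_t(t) = \tfrac12 (1 - \cos(\pi t / t_0)) \quad t < t_t;\qquad
#'   C_t(t) = \tfrac12 (1 - \cos(\pi t_t / t_0)) e^{-(t - t_t)/\tau}
#'   \quad t \ge t_t,} clamped to [0, 1].  `t` is measured from the
#' chamber's `activation_onset`; negative times give 0.
#'
#' @param t time since activation onset (ms); vectorized
#' @param params [active_params()]
#' @return activation level in [0, 1]
#' @export
temporal_activation <- function(t, params = active_params()) {
  ct <- ifelse(t < params$t_t,
               0.5 * (1 - cos(pi * t / params$t0)),
               0.5 * (1 - cos(pi * params$t_t / params$t0)) *
                 exp(-(t - params$t_t) / params$tau))
  ct[t < 0] <- 0
  pmin(pmax(ct, 0), 1)
}

#' Length-dependent calcium activation gate
#'
#' \deqn{g(l) = \frac{Ca_0^2}{Ca_0^2 + ECa_{50}(l)^2},\qquad
#'   ECa_{50} = \frac{(Ca_0)_{max}}{\sqrt{e^{B(l - l_0)} - 1}}.}
#' For `l <= l0` the expression is imaginary and the gate is defined to be 0
#' (the tension-length relation has no tension below the resting length).
#'
#' @param l current sarcomere length (um); vectorized
#' @param params [active_params()]
#' @return gate value in [0, 1)
#' @export
length_dependent_gate <- function(l, params = active_params()) {
  cpp_gate(l, as_actpar(params))
}

#' Active first Piola-Kirchhoff stress
#'
#' \deqn{P_{act} = T_{ref}\, g(l)\, C_t(t)\, e_f \otimes e_{f0}} with
#' \eqn{e_f = F e_{f0} / |F e_{f0}|} the deformed fiber direction and the
#' sarcomere length mapped from the fiber stretch, `l = l_ref |F e_f0|`.
#'
#' @param F 3x3 deformation gradient
#' @param t time since activation onset (ms)
#' @param triad 3x3 triad matrix (row 1 = e_f0)
#' @param params [active_params()]
#' @return list with `P` (kPa), sarcomere length `l` (um), `gate`
#' @export
active_first_pk <- function(F, t, triad = diag(3), params = active_params()) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  act <- params$T_ref * temporal_activation(t, params)
  cpp_active_point(F, triad[1, ], act, as_actpar(params))
}

#' Kinematic quantities at a material point
#'
#' @param F 3x3 deformation gradient
#' @return list with `F`, `J = det F`, right Cauchy--Green `C = F^T F`,
#'   Green--Lagrange `E = (C - I)/2`
#' @export
kinematics_point <- function(F) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  J <- det(F)
  if (J <= 0) stop("inverted state: det(F) <= 0")
  Cr <- t(F) %*% F
  list(F = F, J = J, C = Cr, E = (Cr - diag(3)) / 2)
}
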