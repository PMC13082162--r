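#' Default passive myocardial material parameters
#'
#' Fung-type transversely isotropic strain energy
#' \deqn{W = \tfrac{C}{2}\,(e^Q - 1),\qquad
#'   Q = b_{ff} E_{ff}^2 + b_{xx}(E_{ss}^2+E_{nn}^2+E_{sn}^2+E_{ns}^2)
#'     + b_{fx}(E_{fn}^2+E_{nf}^2+E_{fs}^2+E_{sf}^2),}
#' with \eqn{E_{ij}} the Green--Lagrange strain components in the local
#' fiber/sheet/sheet-normal triad.
#'
#' Defaults are the published reference values for this law family
#' (C = 130 kPa, b_ff = 29.0, b_xx = 26.6, b_fx = 13.3).  Note that a
#' stiffness scale of 130 kPa is two to three orders of magnitude above
#' typical ex-vivo estimates for this law (~0.1--0.5 kPa); the value is kept
#' verbatim as the default but is an ordinary configuration entry, so users
#' can rescale it (see the methods vignette).
#'
#' @param C passive stiffness scale (kPa)
#' @param b_ff,b_xx,b_fx dimensionless anisotropy exponents
#' @return object of class `passive_params`
#' @export
passive_params <- function(C = 130.0, b_ff = 29.0, b_xx = 26.6, b_fx = 13.3) {
  stopifnot(C > 0, b_ff > 0, b_xx > 0, b_fx > 0,
            is.finite(C), is.finite(b_ff), is.finite(b_xx), is.finite(b_fx))
  structure(list(C = C, b_ff = b_ff, b_xx = b_xx, b_fx = b_fx),
            class = "passive_params")
}

#' Default active-stress parameters
#'
#' Phenomenological active fiber tension
#' \deqn{P_{act} = T_{ref}\,\frac{Ca_0^2}{Ca_0^2 + ECa_{50}^2}\,C_t(t)\;
#'   e_f \otimes e_{f0},\qquad
#'   ECa_{50} = \frac{(Ca_0)_{max}}{\sqrt{e^{B(l-l_0)} - 1}},}
#' where `l` is the current sarcomere length, mapped from the fiber stretch
#' as `l = l_ref * |F e_f0|`, and \eqn{C_t} is the temporal activation of
#' [temporal_activation()].  For `l <= l0` the calcium gate is defined as 0
#' (tension cannot be negative or complex).
#'
#' @param T_ref peak active fiber tension (kPa)
#' @param Ca0 peak intracellular calcium concentration (uM)
#' @param Ca0_max calcium concentration at half activation (uM)
#' @param B sarcomere length-tension sensitivity (1/um)
#' @param l0 resting sarcomere length below which no tension develops (um)
#' @param l_ref sarcomere length at zero fiber strain (um); 1.85 um is a
#'   typical unloaded myocardial sarcomere length, giving a shortening
#'   capacity of about 15% before the gate closes
#' @param t0 time to peak tension (ms)
#' @param t_t onset of relaxation (ms)
#' @param tau tension decay time constant (ms)
#' @param activation_onset activation delay within the cycle (ms); the atria
#'   are typically given a late-diastolic onset (720 ms in an 800 ms cycle)
#' @return object of class `active_params`
#' @export
active_params <- function(T_ref = 700.0, Ca0 = 4.35, Ca0_max = 4.35,
                          B = 4.75, l0 = 1.58, l_ref = 1.85,
                          t0 = 275, t_t = 300, tau = 25,
                          activation_onset = 0) {
  stopifnot(T_ref >= 0, t0 > 0, tau > 0, t_t >= 0, l0 > 0, l_ref > 0, B > 0)
  structure(list(T_ref = T_ref, Ca0 = Ca0, Ca0_max = Ca0_max, B = B,
                 l0 = l0, l_ref = l_ref, t0 = t0, t_t = t_t, tau = tau,
                 activation_onset = activation_onset),
            class = "active_params")
}

#' Robin (spring-damper) epicardial boundary-condition parameters
#'
#' Pericardial restraint: traction `-(K_epi u + C_epi u_dot)` on the
#' epicardium with
#' \deqn{K_{epi} = k_n N \otimes N + k_t (I - N\otimes N)} and likewise
#' \eqn{C_{epi}}, i.e. stiff against normal (radial) displacement while
#' permitting low-resistance tangential sliding.  N is the outward unit
#' normal of the reference epicardial surface.
#'
#' There are no published values for these coefficients; the defaults were
#' calibrated once on the idealized ellipsoid fixture to give small epicardial
#' radial motion with free tangential sliding, and should be recalibrated for
#' other geometries.
#'
#' @param k_n,k_t normal/tangential stiffness (kPa/mm)
#' @param c_n,c_t normal/tangential damping (kPa*ms/mm)
#' @return object of class `robin_params`
#' @export
robin_params <- function(k_n = 0.5, k_t = 0.02, c_n = 2.0, c_t = 0.1) {
  stopifnot(k_n >= 0, k_t >= 0, c_n >= 0, c_t >= 0)
  structure(list(k_n = k_n, k_t = k_t, c_n = c_n, c_t = c_t),
            class = "robin_params")
}

#' Pressure-stabilization parameters for the mixed P1-P1 formulation
#'
#' The incompressibility equation is augmented with the element-wise
#' pressure-Laplacian term \eqn{\sum_e (\alpha h_e^2 / 2\mu)\int_e \nabla p
#' \cdot \nabla\delta p\, dV}, which suppresses checkerboard pressure modes
#' of equal-order interpolation.  `alpha` is O(1); `mu` is an effective shear
#' modulus used only for scaling.  When `mu = NULL` it defaults to
#' `C * b_xx / 2`, the small-strain shear stiffness of the passive law.
#'
#' @param alpha dimensionless stabilization constant (default 1)
#' @param mu effective shear modulus (kPa) or NULL for the material default
#' @return object of class `stab_params`
#' @export
stab_params <- function(alpha = 1.0, mu = NULL) {
  stopifnot(alpha >= 0, is.null(mu) || mu > 0)
  structure(list(alpha = alpha, mu = mu), class = "stab_params")
}

resolve_stab_mu <- function(stab, passive) {
  if (!is.null(stab$mu)) stab$mu else passive$C * passive$b_xx / 2
}

as_matpar <- function(passive) {
  c(passive$C, passive$b_ff, passive$b_xx, passive$b_fx)
}
as_actpar <- function(active) {
  c(active$Ca0, active$Ca0_max, active$B, active$l0, active$l_ref)
}

#' Read or write a parameter configuration as YAML
#'
#' Serializes the parameter blocks (passive, active, robin, stabilization,
#' circulation, simulation) to a single YAML file keyed by symbol names, and
#' reads them back into the typed parameter objects.
#'
#' @param config named list of parameter objects
#' @param path file path
#' @return `read_config` returns the named list of parameter objects.
#' @export
write_config <- function(config, path) {
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  for (nm in names(raw)) {
    blk <- raw[[nm]]
    out[[nm]] <- switch(nm,
      passive = do.call(passive_params, blk),
      active = do.call(active_params, blk),
      robin = do.call(robin_params, blk),
      stabilization = do.call(stab_params, blk),
      circulation = do.call(circ_params, blk),
      blk)
  }
  out
}
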