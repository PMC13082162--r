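#' Harmonic transmural coordinate
#'
#' Solves the Laplace equation on the wall with Dirichlet values 0 on the
#' endocardial patch and 1 on the epicardial patch (natural boundary
#' conditions elsewhere).  By the maximum principle the field lies in [0, 1];
#' it parameterizes wall depth for the rule-based fiber assignment.
#'
#' @param mesh a [labeled_mesh()]
#' @param endo,epi patch names
#' @return numeric vector of nodal values in `[0, 1]`
#' @export
transmural_coordinate <- function(mesh, endo = "endo", epi = "epi") {
  for (p in c(endo, epi))
    if (!p %in% names(mesh$surface_patches))
      stop("mesh has no patch named '", p, "'")
  g <- tet_grads(mesh)
  M <- nrow(mesh$tets)
  # P1 stiffness: Ke = vol * G G^T (4x4)
  ii <- jj <- integer(16 * M); xx <- numeric(16 * M); n <- 0L
  for (e in seq_len(M)) {
    Ge <- g$G[e, , ]
    Ke <- g$vol[e] * (Ge %*% t(Ge))
    nd <- mesh$tets[e, ]
    ii[n + 1:16] <- rep(nd, each = 4)
    jj[n + 1:16] <- rep(nd, times = 4)
    xx[n + 1:16] <- as.vector(Ke)
    n <- n + 16L
  }
  N <- nrow(mesh$vertices)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  fixed <- c(patch_nodes(mesh, endo), patch_nodes(mesh, epi))
  vals <- c(rep(0, length(patch_nodes(mesh, endo))),
            rep(1, length(patch_nodes(mesh, epi))))
  free <- setdiff(seq_len(N), fixed)
  t_out <- numeric(N)
  t_out[fixed] <- vals
  rhs <- -K[free, fixed, drop = FALSE] %*% vals
  t_out[free] <- as.vector(Matrix::solve(K[free, free], rhs))
  t_out
}

#' Per-point orthonormal microstructure triads
#'
#' @param triads M x 9 matrix; rows hold (e_f0, e_s0, e_n0) flattened
#' @param helix_angle per-element helix angle (degrees, diagnostic)
#' @return object of class `microstructure_field`
#' @export
microstructure_field <- function(triads, helix_angle = rep(NA_real_, nrow(triads))) {
  stopifnot(is.matrix(triads), ncol(triads) == 9)
  err <- triad_orthonormality_error(triads)
  if (err > 1e-8)
    stop("triads not orthonormal (max deviation ", format(err), ")")
  structure(list(triads = triads, helix_angle = helix_angle),
            class = "microstructure_field")
}

#' @export
print.microstructure_field <- function(x, ...) {
  cat("microstructure_field:", nrow(x$triads), "elements")
  if (!all(is.na(x$helix_angle)))
    cat(sprintf("; helix angle %.1f to %.1f deg",
                min(x$helix_angle), max(x$helix_angle)))
  cat("\n")
  invisible(x)
}

#' Maximum orthonormality deviation of a triad matrix
#' @param triads M x 9 triad matrix
#' @return max |T T^t - I| over all elements
#' @export
triad_orthonormality_error <- function(triads) {
  err <- 0
  for (r in c(1, 4, 7)) {
    v <- triads[, r:(r + 2), drop = FALSE]
    err <- max(err, max(abs(rowSums(v^2) - 1)))
  }
  combs <- list(c(1, 4), c(1, 7), c(4, 7))
  for (cb in combs) {
    d <- rowSums(triads[, cb[1]:(cb[1] + 2), drop = FALSE] *
                 triads[, cb[2]:(cb[2] + 2), drop = FALSE])
    err <- max(err, max(abs(d)))
  }
  err
}

# element-wise local anatomical frame (circumferential, longitudinal,
# transmural) from the transmural field gradient and an apex-base axis.
# Near the apex (grad t parallel to the axis) the circumferential direction
# is degenerate; an arbitrary perpendicular is used there.
local_frames <- function(mesh, transmural, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  g <- tet_grads(mesh)
  M <- nrow(mesh$tets)
  e_t <- e_c <- e_l <- matrix(0, M, 3)
  t_e <- numeric(M)
  n_fallback <- 0L
  for (e in seq_len(M)) {
    nd <- mesh$tets[e, ]
    t_e[e] <- mean(transmural[nd])
    gt <- as.vector(t(g$G[e, , ]) %*% transmural[nd])
    nt <- sqrt(sum(gt^2))
    if (nt < 1e-12) stop("vanishing transmural gradient in element ", e)
    et <- gt / nt
    cc <- pracma_cross(axis, et)
    nc <- sqrt(sum(cc^2))
    if (nc < 1e-6) {
      # apex fallback: any direction perpendicular to e_t
      ref <- if (abs(et[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      cc <- pracma_cross(ref, et)
      nc <- sqrt(sum(cc^2))
      n_fallback <- n_fallback + 1L
    }
    ec <- cc / nc
    el <- pracma_cross(et, ec)
    e_t[e, ] <- et; e_c[e, ] <- ec; e_l[e, ] <- el
  }
  if (n_fallback > 0)
    message("local_frames: circumferential direction degenerate in ",
            n_fallback, " apex element(s); perpendicular fallback used")
  list(e_t = e_t, e_c = e_c, e_l = e_l, t_e = t_e)
}

#' Rule-based ventricular fiber architecture
#'
#' Assigns a fiber helix angle varying linearly across the wall,
#' `alpha(t) = endo_angle + t (epi_angle - endo_angle)` with `t` the
#' transmural coordinate (0 endo, 1 epi); the default +60/-60 degrees is the
#' classical transmural helix.  The fiber direction lies in the local
#' circumferential--longitudinal plane, the sheet direction is transmural
#' (normalized transmural gradient), and the sheet normal completes the
#' right-handed triad `e_n0 = e_f0 x e_s0`.
#'
#' @param mesh a [labeled_mesh()]
#' @param transmural nodal transmural coordinate (from
#'   [transmural_coordinate()]); computed on the fly if NULL
#' @param endo_angle,epi_angle helix angles (degrees) at endo/epicardium
#' @param axis apex-to-base unit axis of the chamber (default +z, matching
#'   the ellipsoid fixtures)
#' @return a [microstructure_field()] with one triad per element
#' @export
assign_ventricular_fibers <- function(mesh, transmural = NULL,
                                      endo_angle = 60, epi_angle = -60,
                                      axis = c(0, 0, 1)) {
  stopifnot(is.finite(endo_angle), is.finite(epi_angle))
  if (sqrt(sum(axis^2)) < 1e-12) stop("undefined apex-base axis")
  if (is.null(transmural)) transmural <- transmural_coordinate(mesh)
  fr <- local_frames(mesh, transmural, axis)
  ang <- (endo_angle + fr$t_e * (epi_angle - endo_angle)) * pi / 180
  ef <- cos(ang) * fr$e_c + sin(ang) * fr$e_l
  es <- fr$e_t
  en <- cbind(ef[, 2] * es[, 3] - ef[, 3] * es[, 2],
              ef[, 3] * es[, 1] - ef[, 1] * es[, 3],
              ef[, 1] * es[, 2] - ef[, 2] * es[, 1])
  microstructure_field(cbind(ef, es, en), helix_angle = ang * 180 / pi)
}

#' Rule-based atrial fiber architecture (configurable blend)
#'
#' Simple mesh-independent rule standing in for anatomically labeled atrial
#' fiber maps: the fiber direction is a normalized blend of the local
#' circumferential and longitudinal directions,
#' `e_f0 ~ (1 - blend) e_c + blend e_l`.  `blend = 0` gives a purely
#' circumferential field, `blend = 1` purely longitudinal.  Chamber-level
#' pressure-volume physiology is insensitive to the fine atrial architecture,
#' which is why the single-parameter rule suffices for the fixtures.
#'
#' @inheritParams assign_ventricular_fibers
#' @param blend longitudinal blend weight in [0, 1]
#' @return a [microstructure_field()]
#' @export
assign_atrial_fibers <- function(mesh, transmural = NULL, blend = 0,
                                 axis = c(0, 0, 1)) {
  stopifnot(blend >= 0, blend <= 1)
  if (is.null(transmural)) transmural <- transmural_coordinate(mesh)
  fr <- local_frames(mesh, transmural, axis)
  ef <- (1 - blend) * fr$e_c + blend * fr$e_l
  ef <- ef / sqrt(rowSums(ef^2))
  # re-orthogonalize the transmural sheet direction against e_f0
  es <- fr$e_t - rowSums(fr$e_t * ef) * ef
  es <- es / sqrt(rowSums(es^2))
  en <- cbind(ef[, 2] * es[, 3] - ef[, 3] * es[, 2],
              ef[, 3] * es[, 1] - ef[, 1] * es[, 3],
              ef[, 1] * es[, 2] - ef[, 2] * es[, 1])
  microstructure_field(cbind(ef, es, en))
}
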