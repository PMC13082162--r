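## Beat records, pressure-volume metrics and strain post-processing.

beat_record_alloc <- function(n) {
  list(time = numeric(n),
       pressure = matrix(NA_real_, n, 4, dimnames = list(NULL, c("lv", "rv", "la", "ra"))),
       volume = matrix(NA_real_, n, 4, dimnames = list(NULL, c("lv", "rv", "la", "ra"))),
       flow = matrix(NA_real_, n, 8, dimnames = list(NULL, c("mv", "av", "sys",
         "sv_ra", "tv", "pvalve", "pul", "pv_la"))),
       vascular = matrix(NA_real_, n, 4, dimnames = list(NULL, c("sa", "sv", "pa", "pv"))))
}

beat_record_push <- function(rec, i, circ) {
  rec$pressure[i, ] <- circ$P[c("lv", "rv", "la", "ra")]
  rec$volume[i, ] <- c(circ$V_lv, circ$V_rv, circ$V_la, circ$V_ra)
  rec$flow[i, ] <- circ$Q
  rec$vascular[i, ] <- c(circ$V_sa, circ$V_sv, circ$V_pa, circ$V_pv)
  rec
}

beat_record_finalize <- function(rec, dt) {
  rec$time <- seq_len(nrow(rec$volume)) * dt
  class(rec) <- "beat_record"
  rec
}

#' Time series of chamber pressures, volumes and valve flows
#'
#' @param time time grid (ms), strictly increasing
#' @param pressure,volume T x 4 matrices with columns lv, rv, la, ra
#'   (mmHg, mL)
#' @param flow optional T x 8 valve/segment flow matrix (mL/ms)
#' @return object of class `beat_record`
#' @export
beat_record <- function(time, pressure, volume, flow = NULL) {
  stopifnot(all(diff(time) > 0), nrow(pressure) == length(time),
            nrow(volume) == length(time),
            all(is.finite(pressure)), all(is.finite(volume)))
  structure(list(time = time, pressure = pressure, volume = volume,
                 flow = flow), class = "beat_record")
}

#' @export
print.beat_record <- function(x, ...) {
  cat("beat_record:", length(x$time), "steps, t in [",
      min(x$time), ",", max(x$time), "] ms\n")
  for (ch in colnames(x$volume)) {
    m <- pv_metrics(x, ch)
    cat(sprintf("  %s: EDV %.1f  ESV %.1f  SV %.1f mL  EF %.1f%%  peak P %.1f mmHg\n",
                toupper(ch), m$EDV, m$ESV, m$SV, m$EF, m$peakP))
  }
  invisible(x)
}

#' Extract the final cycle of a beat record
#'
#' @param rec a `beat_record`
#' @param cycle_period cycle length (ms)
#' @return `beat_record` spanning the last full cycle
#' @export
last_cycle <- function(rec, cycle_period = 800) {
  dt <- rec$time[2] - rec$time[1]
  steps <- round(cycle_period / dt)
  n <- length(rec$time)
  if (n < steps) stop("record shorter than one cycle")
  idx <- (n - steps + 1):n
  out <- list(time = rec$time[idx], pressure = rec$pressure[idx, , drop = FALSE],
              volume = rec$volume[idx, , drop = FALSE],
              flow = if (!is.null(rec$flow)) rec$flow[idx, , drop = FALSE],
              vascular = if (!is.null(rec$vascular)) rec$vascular[idx, , drop = FALSE])
  class(out) <- "beat_record"
  out
}

#' Pressure-volume loop metrics of one chamber
#'
#' End-diastolic volume = max V over the record, end-systolic volume =
#' min V, stroke volume = EDV - ESV, ejection fraction = SV/EDV x 100%,
#' peak pressure = max P.  Invariant under cyclic rotation of the record.
#'
#' @param record a [beat_record()] spanning one period, or a list with
#'   elements `volume` and optionally `pressure` (plain series)
#' @param chamber chamber column for a `beat_record`
#' @return list with EDV, ESV, SV (mL), EF (%), peakP (mmHg)
#' @export
pv_metrics <- function(record, chamber = "lv") {
  if (inherits(record, "beat_record")) {
    V <- record$volume[, chamber]
    P <- record$pressure[, chamber]
  } else {
    V <- record$volume
    P <- record$pressure
  }
  if (!length(V)) stop("empty record")
  EDV <- max(V); ESV <- min(V); SV <- EDV - ESV
  list(EDV = EDV, ESV = ESV, SV = SV,
       EF = if (EDV > 0) 100 * SV / EDV else 0,
       peakP = if (!is.null(P)) max(P) else NA_real_)
}

#' Directional stretch from the right Cauchy-Green tensor
#'
#' \eqn{\lambda = \sqrt{e \cdot C e}} for a unit direction e.
#'
#' @param C_right symmetric positive-definite 3x3 right Cauchy--Green tensor
#' @param e unit direction vector
#' @return stretch ratio
#' @export
directional_stretch <- function(C_right, e) {
  stopifnot(is.matrix(C_right), all(dim(C_right) == c(3, 3)))
  if (max(abs(C_right - t(C_right))) > 1e-8) stop("C must be symmetric")
  ev <- eigen(C_right, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("C must be positive definite")
  if (abs(sum(e^2) - 1) > 1e-8) stop("e must be a unit vector")
  sqrt(as.numeric(t(e) %*% C_right %*% e))
}

#' Directional Euler-Almansi strain in percent
#'
#' \eqn{\varepsilon = \tfrac12 (1 - 1/\lambda^2) \times 100\%}; shortening
#' (`lambda < 1`) gives negative strain.
#'
#' @param lambda stretch ratio(s), > 0
#' @return strain in percent
#' @export
almansi_strain_pct <- function(lambda) {
  if (any(lambda <= 0)) stop("stretch must be positive")
  50 * (1 - 1 / lambda^2)
}

#' Anatomical strain frame
#'
#' Per-element longitudinal and circumferential unit vectors built from the
#' same apex-base frame as the fiber rule, plus element reference volumes
#' for wall-volume-weighted averaging.
#'
#' @param mesh a [labeled_mesh()]
#' @param transmural nodal transmural coordinate (computed if NULL)
#' @param axis apex-to-base axis
#' @return object of class `strain_frame` with `e_l`, `e_c` (M x 3), `vol`
#' @export
strain_frame <- function(mesh, transmural = NULL, axis = c(0, 0, 1)) {
  if (is.null(transmural)) transmural <- transmural_coordinate(mesh)
  fr <- local_frames(mesh, transmural, axis)
  structure(list(e_l = fr$e_l, e_c = fr$e_c,
                 vol = tet_signed_volumes(mesh$vertices, mesh$tets)),
            class = "strain_frame")
}

# per-element deformation gradients for one displacement snapshot
element_def_gradients <- function(mesh, u, grads = NULL) {
  if (is.null(grads)) grads <- tet_grads(mesh)
  M <- nrow(mesh$tets)
  um <- matrix(u, ncol = 3, byrow = TRUE)
  F_all <- array(0, c(M, 3, 3))
  for (e in seq_len(M)) {
    Ue <- um[mesh$tets[e, ], , drop = FALSE]      # 4 x 3
    F_all[e, , ] <- diag(3) + t(Ue) %*% grads$G[e, , ]
  }
  F_all
}

#' Global strain waveforms relative to end-diastole
#'
#' For each snapshot, the relative directional stretch per element is
#' \eqn{\lambda(t) = |F(t) a_0| / |F_{ED}\, a_0|} for the longitudinal and
#' circumferential directions; the directional Euler--Almansi strain
#' [almansi_strain_pct()] is averaged over the wall weighted by reference
#' element volume.  Waveforms are exactly zero at the end-diastolic
#' reference snapshot (identified as the maximum-cavity-volume snapshot when
#' `ed_index` is NULL).
#'
#' @param mesh a [labeled_mesh()]
#' @param snapshots list with `times` (ms) and `u` (list of displacement
#'   vectors)
#' @param frame a [strain_frame()]
#' @param chamber chamber used for ED detection
#' @param ed_index optional explicit end-diastolic snapshot index
#' @return list with `time`, `eps_ll`, `eps_cc` (percent), `ed_index`
#' @export
strain_waveforms <- function(mesh, snapshots, frame, chamber = "lv",
                             ed_index = NULL) {
  ns <- length(snapshots$u)
  if (ns < 1) stop("no snapshots")
  if (is.null(ed_index)) {
    vols <- vapply(snapshots$u, function(u) cavity_volume(mesh, chamber, u), 0)
    ed_index <- which.max(vols)
  }
  if (ed_index < 1 || ed_index > ns) stop("missing end-diastolic frame")
  grads <- tet_grads(mesh)
  M <- nrow(mesh$tets)
  F_ed <- element_def_gradients(mesh, snapshots$u[[ed_index]], grads)
  lam_ed_l <- lam_ed_c <- numeric(M)
  for (e in seq_len(M)) {
    lam_ed_l[e] <- sqrt(sum((F_ed[e, , ] %*% frame$e_l[e, ])^2))
    lam_ed_c[e] <- sqrt(sum((F_ed[e, , ] %*% frame$e_c[e, ])^2))
  }
  w <- frame$vol / sum(frame$vol)
  eps_ll <- eps_cc <- numeric(ns)
  for (s in seq_len(ns)) {
    F_t <- element_def_gradients(mesh, snapshots$u[[s]], grads)
    ll <- cc <- numeric(M)
    for (e in seq_len(M)) {
      ll[e] <- sqrt(sum((F_t[e, , ] %*% frame$e_l[e, ])^2)) / lam_ed_l[e]
      cc[e] <- sqrt(sum((F_t[e, , ] %*% frame$e_c[e, ])^2)) / lam_ed_c[e]
    }
    eps_ll[s] <- sum(w * almansi_strain_pct(ll))
    eps_cc[s] <- sum(w * almansi_strain_pct(cc))
  }
  list(time = snapshots$times, eps_ll = eps_ll, eps_cc = eps_cc,
       ed_index = ed_index)
}

seg_intersect <- function(p1, p2, p3, p4) {
  # proper intersection of open segments p1p2 and p3p4; returns point or NULL
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-14) return(NULL)
  b <- p3 - p1
  s <- (b[1] * d2[2] - b[2] * d2[1]) / den
  u <- (b[1] * d1[2] - b[2] * d1[1]) / den
  eps <- 1e-9
  if (s <= eps || s >= 1 - eps || u <= eps || u >= 1 - eps) return(NULL)
  list(point = p1 + s * d1, s = s, u = u)
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Detect the atrial "figure of 8" pressure-volume pattern
#'
#' Searches the closed PV polyline for a self-intersection; if found, splits
#' the trajectory there into the two sub-loops (the passive V-loop and the
#' active A-loop) and reports their absolute shoelace areas, the larger one
#' as `A_loop_area` and the smaller as `V_loop_area`.
#'
#' @param record a [beat_record()] spanning one period
#' @param chamber atrial chamber ("la" or "ra")
#' @return list with `crossing_found`, `A_loop_area`, `V_loop_area`
#'   (mmHg*mL; `V_loop_area` is NA without a crossing, where the single
#'   loop area is reported as `A_loop_area`)
#' @export
detect_atrial_figure8 <- function(record, chamber = "la") {
  V <- record$volume[, chamber]
  P <- record$pressure[, chamber]
  n <- length(V)
  pts <- cbind(V, P)
  # close the loop
  pts <- rbind(pts, pts[1, ])
  for (i in 1:(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- (i + 2):jmax
    for (j in js) {
      hit <- seg_intersect(pts[i, ], pts[i + 1, ], pts[j, ], pts[j + 1, ])
      if (!is.null(hit)) {
        # loop 1: crossing -> i+1 ... j -> crossing
        x1 <- c(hit$point[1], pts[(i + 1):j, 1])
        y1 <- c(hit$point[2], pts[(i + 1):j, 2])
        # loop 2: crossing -> j+1 ... n, 1 ... i -> crossing
        idx2 <- c(if (j + 1 <= n) (j + 1):n, 1:i)
        x2 <- c(hit$point[1], pts[idx2, 1])
        y2 <- c(hit$point[2], pts[idx2, 2])
        a1 <- abs(shoelace_area(x1, y1))
        a2 <- abs(shoelace_area(x2, y2))
        return(list(crossing_found = TRUE,
                    A_loop_area = max(a1, a2), V_loop_area = min(a1, a2)))
      }
    }
  }
  list(crossing_found = FALSE,
       A_loop_area = abs(shoelace_area(V, P)), V_loop_area = NA_real_)
}

#' Write a beat record to CSV
#'
#' Columns: `time_ms`, `p_<ch>_mmhg`, `v_<ch>_ml` for the four chambers and
#' `q_<name>_ml_per_ms` for the valve/segment flows.
#'
#' @param record a [beat_record()]
#' @param path output file
#' @return the path, invisibly
#' @export
write_beat_record_csv <- function(record, path) {
  df <- data.frame(time_ms = record$time)
  for (ch in colnames(record$pressure))
    df[[paste0("p_", ch, "_mmhg")]] <- record$pressure[, ch]
  for (ch in colnames(record$volume))
    df[[paste0("v_", ch, "_ml")]] <- record$volume[, ch]
  if (!is.null(record$flow))
    for (q in colnames(record$flow))
      df[[paste0("q_", q, "_ml_per_ms")]] <- record$flow[, q]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Summarize chamber function as JSON
#'
#' @param record a [beat_record()]
#' @param path output file (NULL returns the JSON string)
#' @return path or JSON string
#' @export
write_run_summary_json <- function(record, path = NULL) {
  out <- lapply(colnames(record$volume), function(ch) pv_metrics(record, ch))
  names(out) <- colnames(record$volume)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
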