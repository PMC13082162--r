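test_that("directional stretch follows the tensor algebra", {
  expect_equal(directional_stretch(diag(3), c(1, 0, 0)), 1)
  Fm <- diag(c(1.2, 1, 1))
  expect_equal(directional_stretch(t(Fm) %*% Fm, c(1, 0, 0)), 1.2)
  # simple shear oracle: F = I + g x(x)y stretches y-lines by sqrt(1+g^2)
  g <- 0.3
  Fs <- diag(3); Fs[1, 2] <- g
  expect_equal(directional_stretch(t(Fs) %*% Fs, c(0, 1, 0)), sqrt(1 + g^2),
               tolerance = 1e-12)
  expect_error(directional_stretch(diag(c(1, -1, 1)), c(1, 0, 0)), "positive")
  expect_error(directional_stretch(diag(3), c(1, 1, 0)), "unit")
})

test_that("directional Euler-Almansi strain matches its closed form", {
  expect_equal(almansi_strain_pct(1), 0)
  expect_equal(almansi_strain_pct(1.2), 50 * (1 - 1 / 1.44))
  expect_equal(almansi_strain_pct(1.2), 15.2778, tolerance = 1e-4)
  expect_equal(almansi_strain_pct(0.8), -28.125, tolerance = 1e-10)
  expect_error(almansi_strain_pct(0), "positive")
  # monotone increasing with supremum 50%
  lam <- seq(0.3, 30, length.out = 500)
  eps <- almansi_strain_pct(lam)
  expect_true(all(diff(eps) > 0))
  expect_true(all(eps < 50))
  expect_gt(almansi_strain_pct(1e4), 49.99)
})

test_that("pv metrics reproduce loop quantities and are rotation-invariant", {
  t <- seq_len(100)
  V <- 100 + 35 * sin(2 * pi * t / 100)         # max 135, min 65
  P <- 60 + 50 * cos(2 * pi * t / 100)
  rec <- beat_record(t, cbind(lv = P, rv = P, la = P, ra = P),
                     cbind(lv = V, rv = V, la = V, ra = V))
  m <- pv_metrics(rec, "lv")
  expect_equal(m$EDV, max(V)); expect_equal(m$ESV, min(V))
  expect_equal(m$SV, max(V) - min(V))
  expect_equal(m$EF, 100 * (max(V) - min(V)) / max(V))
  # cyclic rotation of the record leaves all metrics unchanged
  sh <- c(37:100, 1:36)
  rec2 <- beat_record(t, rec$pressure[sh, ], rec$volume[sh, ])
  expect_equal(pv_metrics(rec2, "lv"), m)
  # degenerate series
  m0 <- pv_metrics(list(volume = rep(80, 10), pressure = rep(5, 10)))
  expect_equal(m0$SV, 0); expect_equal(m0$EF, 0)
  expect_error(pv_metrics(list(volume = numeric(0))), "empty")
})

test_that("strain waveforms are zero at end-diastole and exact for homogeneous fields", {
  mesh <- make_box_mesh(2, 2, 2)
  vols <- heartfem:::tet_signed_volumes(mesh$vertices, mesh$tets)
  frame <- structure(list(e_l = matrix(rep(c(1, 0, 0), nrow(mesh$tets)),
                                       ncol = 3, byrow = TRUE),
                          e_c = matrix(rep(c(0, 1, 0), nrow(mesh$tets)),
                                       ncol = 3, byrow = TRUE),
                          vol = vols), class = "strain_frame")
  # homogeneous F(t) = diag(lam(t), 1, 1)
  lam_t <- c(1.00, 1.08, 0.95, 0.90, 1.02)
  snaps <- list(times = (0:4) * 100,
                u = lapply(lam_t, function(l)
                  as.vector(t(mesh$vertices %*% diag(c(l - 1, 0, 0))))))
  sw <- strain_waveforms(mesh, snaps, frame, ed_index = 2)  # lam max = 1.08
  expect_equal(sw$eps_ll, almansi_strain_pct(lam_t / 1.08), tolerance = 1e-9)
  expect_equal(sw$eps_cc, rep(0, 5), tolerance = 1e-12)
  expect_identical(sw$eps_ll[2], 0)
  # all-identical snapshots -> identically zero waveforms
  snaps0 <- list(times = 0:2, u = rep(list(numeric(3 * nrow(mesh$vertices))), 3))
  sw0 <- strain_waveforms(mesh, snaps0, frame, ed_index = 1)
  expect_equal(sw0$eps_ll, rep(0, 3))
  expect_equal(sw0$eps_cc, rep(0, 3))
  # systolic shortening gives negative strain
  expect_lt(sw$eps_ll[4], 0)
  expect_error(strain_waveforms(mesh, snaps, frame, ed_index = 99), "frame")
})

test_that("figure-of-eight detection splits loops with shoelace areas", {
  # synthetic lemniscate-like PV curve with known sub-loop areas; phase
  # offset keeps the self-crossing off the sampled vertices
  th <- seq(0, 2 * pi, length.out = 241)[-241] + 0.013
  V <- 50 + 20 * sin(th)
  P <- 8 + 4 * sin(2 * th)   # crosses itself at th = 0/pi
  rec <- list(volume = cbind(la = V), pressure = cbind(la = P))
  f8 <- detect_atrial_figure8(rec, "la")
  expect_true(f8$crossing_found)
  # shoelace oracle on the two halves (crossing at V = 50, P = 8)
  half <- function(idx) abs(heartfem:::shoelace_area(V[idx], P[idx]))
  a1 <- half(th < pi); a2 <- half(th >= pi)
  expect_equal(f8$A_loop_area, max(a1, a2), tolerance = 0.02 * max(a1, a2))
  expect_equal(f8$V_loop_area, min(a1, a2), tolerance = 0.02 * max(a1, a2))
  # simple convex loop: no crossing, single loop area reported
  V2 <- 60 + 10 * cos(th); P2 <- 10 + 5 * sin(th)
  f8b <- detect_atrial_figure8(list(volume = cbind(la = V2),
                                    pressure = cbind(la = P2)), "la")
  expect_false(f8b$crossing_found)
  expect_equal(f8b$A_loop_area, pi * 10 * 5, tolerance = 0.01 * pi * 50)
  expect_true(is.na(f8b$V_loop_area))
})

test_that("atrial records from the surrogate loop show the figure-of-eight", {
  rec <- suppressWarnings(run_0d_only(cycles = 10))
  fc <- last_cycle(rec)
  for (ch in c("la", "ra")) {
    f8 <- detect_atrial_figure8(fc, ch)
    expect_true(f8$crossing_found)
    expect_gt(f8$A_loop_area, 0)
    expect_gt(f8$V_loop_area, 0)
    # the passive V-loop is smaller than the active A-loop
    expect_lt(f8$V_loop_area, f8$A_loop_area)
  }
})

test_that("beat records export to CSV and JSON summaries", {
  rec <- suppressWarnings(run_0d_only(cycles = 2))
  f <- tempfile(fileext = ".csv")
  write_beat_record_csv(last_cycle(rec), f)
  df <- read.csv(f)
  expect_equal(nrow(df), 800)
  expect_true(all(c("time_ms", "p_lv_mmhg", "v_lv_ml", "q_av_ml_per_ms")
                  %in% names(df)))
  js <- jsonlite::fromJSON(write_run_summary_json(last_cycle(rec)))
  expect_equal(js$lv$SV, pv_metrics(last_cycle(rec), "lv")$SV,
               tolerance = 1e-9)
})
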