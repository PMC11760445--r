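# Cycle segmentation, rigid-body fitting and the micromotion outcomes.

ring_pts <- function(x, r, n = 6L, off = 0) {
  phi <- (off + seq(0, by = 60, length.out = n)) * pi / 180
  cbind(rep(x, n), r * cos(phi), r * sin(phi))
}

# hand-built recording: both bodies undergo the same world motion
common_mode_recording <- function(n_frames = 90L) {
  t <- (seq_len(n_frames) - 1) / 5
  shear <- 350 * sin(2 * pi * t / 6)
  sph <- ring_pts(5, 18, off = 45)
  rim <- ring_pts(0, 15)
  mk <- function(base) {
    out <- array(0, c(n_frames, nrow(base), 3L))
    for (i in seq_len(n_frames)) {
      th <- 0.02 * sin(2 * pi * t[i] / 6)
      R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
      out[i, , ] <- base %*% t(R) +
        matrix(c(0.5, -0.2, 0.3) * sin(t[i]), nrow(base), 3L, byrow = TRUE)
    }
    out
  }
  marker_recording(t, list(glenosphere = mk(sph), glenoid_rim = mk(rim)),
                   shear, "pre",
                   meta = list(sample_hz = 5, shear_freq_hz = 1 / 6,
                               n_cycles = n_frames / 30))
}

test_that("clean sinusoidal shear segments into equal full cycles", {
  rec <- generate_marker_recording(bench_spec(seed = 1), "pre")
  w <- segment_cycles(rec)
  expect_identical(nrow(w), 25L)
  expect_true(all(w$end - w$start + 1L == 30L))
  expect_identical(w$start[1L], 1L)
  expect_identical(w$end[25L], 750L)
})

test_that("constant shear channel falls back to fixed-length windows", {
  rec <- generate_marker_recording(bench_spec(seed = 1), "pre")
  rec$shear_n <- rep(0, length(rec$shear_n))
  w <- segment_cycles(rec)
  expect_identical(nrow(w), 25L)
  expect_true(all(w$end - w$start + 1L == 30L))
  rec$meta$shear_freq_hz <- NULL
  expect_error(segment_cycles(rec), "frequency")
  w2 <- segment_cycles(rec, expected_freq_hz = 1 / 6)
  expect_identical(w2$start, w$start)
})

test_that("noisy shear channels segment like the noiseless oracle", {
  rec <- generate_marker_recording(bench_spec(seed = 2), "pre")
  clean <- segment_cycles(rec)
  set.seed(5)
  rec$shear_n <- rec$shear_n + rnorm(length(rec$shear_n), 0, 1)
  expect_identical(segment_cycles(rec), clean)
})

test_that("rigid-body fit recovers exact transforms and flags degeneracy", {
  X <- ring_pts(0, 15)
  fit_t <- fit_rigid_body(X, X + matrix(c(0.01, 0, 0), 6L, 3L, byrow = TRUE))
  expect_equal(fit_t$t, c(0.01, 0, 0), tolerance = 1e-12)
  expect_equal(fit_t$R, diag(3), tolerance = 1e-12)
  expect_lt(fit_t$rms, 1e-12)

  th <- 1 * pi / 180
  R1 <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  fit_r <- fit_rigid_body(X, X %*% t(R1))
  ang <- acos((sum(diag(fit_r$R)) - 1) / 2) * 180 / pi
  expect_equal(ang, 1, tolerance = 1e-9)
  expect_equal(det(fit_r$R), 1, tolerance = 1e-12)

  collinear <- cbind(1:5, 1:5, 1:5)
  expect_error(fit_rigid_body(collinear, collinear), "collinear")
  expect_error(fit_rigid_body(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("noisy rigid fits keep mean translation error below 3 sigma / sqrt(n)", {
  set.seed(7)
  X <- ring_pts(0, 15)
  sd_mm <- 2.8e-3
  err <- replicate(300, {
    f <- fit_rigid_body(X, X + matrix(rnorm(18, 0, sd_mm), 6L, 3L))
    sqrt(sum(f$t^2))
  })
  expect_lt(mean(err), 3 * sd_mm / sqrt(6))
})

test_that("relative measures vanish in a rigid or common-mode world", {
  rigid <- generate_marker_recording(noiseless_bench(
    elastic_amplitude_um = 0, rot_amplitude_deg = 0), "pre")
  expect_lt(max(abs(relative_displacement_series(rigid))), 1e-9)
  expect_lt(max(abs(rotation_series(rigid))), 1e-9)

  cm <- common_mode_recording()
  expect_lt(max(abs(relative_displacement_series(cm))), 1e-6)
  expect_lt(max(abs(rotation_series(cm))), 1e-8)
})

test_that("injected amplitudes are recovered exactly without noise", {
  for (amp in c(10, 120)) {
    rec <- generate_marker_recording(noiseless_bench(
      elastic_amplitude_um = amp, rot_amplitude_deg = 0.3), "pre")
    w <- segment_cycles(rec)
    expect_equal(cycle_range_mean(relative_displacement_series(rec), w),
                 amp, tolerance = 1e-6)
    expect_equal(cycle_range_mean(rotation_series(rec), w), 0.3,
                 tolerance = 1e-6)
  }
})

test_that("cycle range mean matches the exhaustive per-window scan", {
  set.seed(9)
  series <- cumsum(rnorm(300))
  w <- data.frame(start = seq(1L, 271L, by = 30L),
                  end = seq(30L, 300L, by = 30L))
  manual <- 0
  for (i in seq_len(nrow(w))) {
    lo <- Inf; hi <- -Inf
    for (j in w$start[i]:w$end[i]) {
      lo <- min(lo, series[j]); hi <- max(hi, series[j])
    }
    manual <- manual + (hi - lo)
  }
  expect_equal(cycle_range_mean(series, w), manual / nrow(w))
  expect_equal(cycle_range_mean(rep(2, 100), w[1:2, ]), 0)
  expect_error(cycle_range_mean(series, data.frame(start = 1L, end = 400L)),
               "outside")
})

test_that("interface split reflects the configured graft share", {
  rec <- generate_marker_recording(noiseless_bench(graft_split = 0.53),
                                   "pre")
  sp <- interface_split(rec)
  expect_equal(sp$implant_graft_pct, 53, tolerance = 1e-9)
  expect_equal(sp$graft_glenoid_pct, 47, tolerance = 1e-9)

  even <- generate_marker_recording(noiseless_bench(graft_split = 0.5),
                                    "pre")
  expect_equal(interface_split(even)$implant_graft_pct, 50,
               tolerance = 1e-9)

  locked <- generate_marker_recording(noiseless_bench(graft_split = 1),
                                      "pre")
  sp_locked <- interface_split(locked)
  expect_equal(sp_locked$implant_graft_pct, 100, tolerance = 1e-6)
  expect_equal(sp_locked$graft_glenoid_pct, 0, tolerance = 1e-6)

  no_graft <- generate_marker_recording(noiseless_bench(), "pre")
  expect_error(interface_split(no_graft), "graft")
})

test_that("stability outcome assembles pre/post deltas and the 150 um flag", {
  same <- noiseless_bench(post_added_um = 0, permanent_offset_um = 0,
                          rot_post_added_deg = 0)
  out0 <- stability_outcome(generate_marker_recording(same, "pre"),
                            generate_marker_recording(same, "post"))
  expect_equal(out0$micromotion_delta, 0, tolerance = 1e-9)
  expect_equal(out0$rotation_delta, 0, tolerance = 1e-9)
  expect_false(out0$exceeds_150um)

  plus20 <- noiseless_bench(elastic_amplitude_um = 60, post_added_um = 20)
  out20 <- stability_outcome(generate_marker_recording(plus20, "pre"),
                             generate_marker_recording(plus20, "post"))
  expect_equal(out20$micromotion_delta, 20, tolerance = 1e-6)

  big <- noiseless_bench(elastic_amplitude_um = 150, post_added_um = 10)
  outb <- stability_outcome(generate_marker_recording(big, "pre"),
                            generate_marker_recording(big, "post"))
  expect_true(outb$exceeds_150um)

  other <- noiseless_bench(n_cycles = 10L)
  expect_error(stability_outcome(generate_marker_recording(plus20, "pre"),
                                 generate_marker_recording(other, "post")),
               "differ")
  expect_error(stability_outcome(generate_marker_recording(plus20, "post"),
                                 generate_marker_recording(plus20, "post")),
               "pre/post")
})
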