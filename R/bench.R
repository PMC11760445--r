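# Synthetic optical marker recordings of the rocking-horse bench test.

#' Marker recording container
#'
#' Time-stamped labelled 3-D marker tracks for the rigid bodies watched by
#' the optical system during a rocking-horse test: the glenosphere, the
#' glenoid rim and, for bone-graft constructs, the graft, together with the
#' per-frame shear load channel.
#'
#' @param time_s Numeric vector of frame times (s).
#' @param bodies Named list of arrays `[n_frames, n_markers, 3]` (mm); must
#'   contain `glenosphere` and `glenoid_rim`, optionally `graft`; every
#'   body needs >= 2 markers (>= 3 for rigid-body fitting).
#' @param shear_n Per-frame shear load (N), same length as `time_s`.
#' @param phase `"pre"` or `"post"` (relative to fatigue loading).
#' @param meta List of protocol metadata (sampling rate, cycle frequency,
#'   cycle count, loads); used for cycle-window fallbacks and
#'   configuration-matching checks.
#' @return A list of class `marker_recording`.
#' @export
marker_recording <- function(time_s, bodies, shear_n,
                             phase = c("pre", "post"), meta = list()) {
  phase <- match.arg(phase)
  n <- length(time_s)
  if (n < 2L) stop("recording needs at least 2 frames", call. = FALSE)
  if (length(shear_n) != n)
    stop("shear channel length must match frame count", call. = FALSE)
  if (!all(c("glenosphere", "glenoid_rim") %in% names(bodies)))
    stop("bodies must include glenosphere and glenoid_rim", call. = FALSE)
  for (nm in names(bodies)) {
    b <- bodies[[nm]]
    if (!is.array(b) || length(dim(b)) != 3L || dim(b)[3L] != 3L)
      stop(sprintf("body '%s' must be an [frames, markers, 3] array", nm),
           call. = FALSE)
    if (dim(b)[1L] != n)
      stop(sprintf("body '%s' track length differs from time base", nm),
           call. = FALSE)
    if (dim(b)[2L] < 2L)
      stop(sprintf("body '%s' needs at least 2 markers", nm), call. = FALSE)
    if (anyNA(b))
      stop(sprintf("body '%s' has missing frames", nm), call. = FALSE)
  }
  structure(list(time_s = time_s, bodies = bodies, shear_n = shear_n,
                 phase = phase, meta = meta),
            class = "marker_recording")
}

#' @export
print.marker_recording <- function(x, ...) {
  cat(sprintf("<marker_recording> %s phase: %d frames, bodies: %s\n",
              x$phase, length(x$time_s),
              paste(sprintf("%s(%d)", names(x$bodies),
                            vapply(x$bodies, function(b) dim(b)[2L],
                                   integer(1L))), collapse = ", ")))
  invisible(x)
}

#' Marker ring helper: n markers on a circle in a plane x = const
#' @noRd
marker_ring <- function(x_mm, radius_mm, n = 6L, offset_deg = 0) {
  phi <- (offset_deg + seq(0, by = 60, length.out = n)) * pi / 180
  cbind(x = rep(x_mm, n), y = radius_mm * cos(phi), z = radius_mm * sin(phi))
}

#' Generate a synthetic rocking-horse marker recording
#'
#' Emulates one optical recording phase of the bench test. The glenoid rim
#' is stationary; the glenosphere undergoes a per-cycle relative motion
#' locked to the sinusoidal shear channel: a superior translation ramping
#' 0 -> amplitude -> 0 within each cycle plus a rotational oscillation about
#' the implant axis, with the post-fatigue phase adding a permanent offset
#' and enlarged amplitudes. When `graft_split` is set, a separately tracked
#' graft body carries `1 - graft_split` of the translation, so the
#' implant-graft interface sees fraction `graft_split` of the total motion.
#' Optical noise is added independently per marker coordinate.
#'
#' Markers sit on configurable rings: six on the glenosphere equator, six
#' on the glenoid rim, six on the graft. The implant axis passes through
#' the baseplate centre, so the rotational component adds no translation at
#' the default displacement reference point.
#'
#' @param spec A [bench_spec()].
#' @param phase `"pre"` or `"post"`.
#' @return A [marker_recording()].
#' @export
generate_marker_recording <- function(spec, phase = c("pre", "post")) {
  spec <- validate_bench_spec(unclass(spec))
  if (!is.character(phase) || !all(phase %in% c("pre", "post")))
    stop("phase must be 'pre' or 'post'", call. = FALSE)
  phase <- match.arg(phase)
  set.seed(specimen_seed(spec$seed, if (phase == "post") 1L else 0L))

  n_frames <- as.integer(round(spec$n_cycles * spec$sample_hz /
                                 spec$shear_freq_hz))
  t <- (seq_len(n_frames) - 1) / spec$sample_hz
  omega <- 2 * pi * spec$shear_freq_hz
  shear <- spec$shear_n * sin(omega * t)

  amp_um <- spec$elastic_amplitude_um +
    if (phase == "post") spec$post_added_um else 0
  off_um <- if (phase == "post") spec$permanent_offset_um else 0
  rot_deg <- spec$rot_amplitude_deg +
    if (phase == "post") spec$rot_post_added_deg else 0

  # within-cycle envelope 0 -> 1 -> 0, so per-cycle range = amplitude
  env <- (1 - cos(omega * t)) / 2
  u_mm <- (off_um + amp_um * env) / 1000          # superior translation
  theta <- rot_deg * env * pi / 180               # rotation about +x axis

  rim0 <- marker_ring(0, 15, offset_deg = 0)
  sph0 <- marker_ring(5, 18, offset_deg = 45)
  n_frames_idx <- seq_len(n_frames)

  make_tracks <- function(base, translate_mm, rotate = FALSE) {
    nm <- nrow(base)
    out <- array(0, c(n_frames, nm, 3L),
                 dimnames = list(NULL, paste0("m", seq_len(nm)),
                                 c("x_mm", "y_mm", "z_mm")))
    for (i in n_frames_idx) {
      p <- base
      if (rotate) {
        ct <- cos(theta[i]); st <- sin(theta[i])
        p <- cbind(p[, 1L], p[, 2L] * ct - p[, 3L] * st,
                   p[, 2L] * st + p[, 3L] * ct)
      }
      p[, 3L] <- p[, 3L] + translate_mm[i]
      out[i, , ] <- p
    }
    out
  }

  bodies <- list(
    glenosphere = make_tracks(sph0, u_mm, rotate = TRUE),
    glenoid_rim = make_tracks(rim0, rep(0, n_frames)))
  if (!is.null(spec$graft_split)) {
    graft0 <- marker_ring(2.5, 16, offset_deg = 20)
    bodies$graft <- make_tracks(graft0, (1 - spec$graft_split) * u_mm)
  }

  if (spec$marker_noise_um > 0) {
    sd_mm <- spec$marker_noise_um / 1000
    for (nm in names(bodies))
      bodies[[nm]] <- bodies[[nm]] +
        stats::rnorm(length(bodies[[nm]]), 0, sd_mm)
  }

  marker_recording(time_s = t, bodies = bodies, shear_n = shear,
                   phase = phase,
                   meta = list(sample_hz = spec$sample_hz,
                               shear_freq_hz = spec$shear_freq_hz,
                               n_cycles = spec$n_cycles,
                               compression_n = spec$compression_n,
                               shear_n = spec$shear_n,
                               fatigue_cycles = spec$fatigue_cycles,
                               graft_split = spec$graft_split,
                               marker_noise_um = spec$marker_noise_um))
}
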