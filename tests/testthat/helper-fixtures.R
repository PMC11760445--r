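# Shared fixture builders: compact phantoms that fit small grids, and a
# noiseless bench configuration for closed-form checks.

small_phantom_spec <- function(...) {
  defaults <- list(grid_shape = c(40L, 40L, 40L), glenoid_width_mm = 12,
                   glenoid_height_mm = 10, vault_depth_mm = 9,
                   articular_offset_mm = 2.4)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

tiny_phantom_spec <- function(...) {
  defaults <- list(grid_shape = c(32L, 32L, 32L), glenoid_width_mm = 10,
                   glenoid_height_mm = 9, vault_depth_mm = 8,
                   articular_offset_mm = 1.8, cortical_thickness_vox = 1L)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

noiseless_bench <- function(...) {
  defaults <- list(marker_noise_um = 0)
  do.call(bench_spec, utils::modifyList(defaults, list(...)))
}

# exhaustive voxel-count BV/TV oracle: explicit loop, no vectorized reuse
# of the implementation under test
brute_force_bvtv <- function(values, mask, threshold) {
  idx <- which(mask)
  hits <- 0L
  for (i in idx) if (values[i] >= threshold) hits <- hits + 1L
  hits / length(idx)
}

# independent contact-fraction oracle: pointwise gap count over the same
# sample grid, written as an explicit loop
brute_force_contact <- function(surface_fun, diameter_mm, wedge_angle_deg,
                                rotation_deg, tol_mm, n_grid = 41L) {
  r <- diameter_mm / 2
  xs <- seq(-r, r, length.out = n_grid)
  gaps <- c()
  phi <- rotation_deg * pi / 180
  for (x in xs) for (y in xs) {
    if (x^2 + y^2 > r^2) next
    s <- surface_fun(x, y)
    if (!is.finite(s)) next
    w <- (x * cos(phi) + y * sin(phi) + r) * tan(wedge_angle_deg * pi / 180)
    gaps <- c(gaps, w - s)
  }
  gaps <- gaps - min(gaps)
  mean(gaps <= tol_mm)
}
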