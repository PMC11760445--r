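# Synthetic glenoid CT phantoms with analytic ground truth.

#' Calibration anchor densities (mgHA/cm^3) for air, fat and muscle
#'
#' Reference-tissue bone-mineral-density equivalents used by the
#' patient-specific densitometric calibration: grayscale values sampled in
#' air, subcutaneous fat and muscle are pinned to these densities.
#' @export
BMD_ANCHORS <- c(air = -840, fat = -80, muscle = 30)

#' Intrinsic scanner grayscale for a given BMD
#'
#' Piecewise-linear response through the (anchor BMD, reference grayscale)
#' pairs, with terminal-segment slopes continued beyond the anchors. This is
#' the exact inverse of the calibration map fitted from the same reference
#' grayscales, which is what makes phantom densitometry invertible.
#' @noRd
bmd_to_grayscale <- function(bmd, ref_grayscale) {
  piecewise_two_segment(bmd,
                        x_anchor = BMD_ANCHORS,
                        y_anchor = ref_grayscale[c("air", "fat", "muscle")])
}

#' Two-segment piecewise-linear map through three anchors
#'
#' Segment 1 (through air and fat anchors) applies below the fat anchor and
#' extrapolates below air; segment 2 (fat-muscle) applies above and
#' extrapolates above muscle.
#' @noRd
piecewise_two_segment <- function(x, x_anchor, y_anchor) {
  s1 <- (y_anchor[[2L]] - y_anchor[[1L]]) / (x_anchor[[2L]] - x_anchor[[1L]])
  s2 <- (y_anchor[[3L]] - y_anchor[[2L]]) / (x_anchor[[3L]] - x_anchor[[2L]])
  ifelse(x <= x_anchor[[2L]],
         y_anchor[[2L]] + (x - x_anchor[[2L]]) * s1,
         y_anchor[[2L]] + (x - x_anchor[[2L]]) * s2)
}

#' Separable box smoothing of a 3-D array (edge replication)
#' @noRd
smooth3d_box <- function(a, reps = 2L) {
  d <- dim(a)
  for (r in seq_len(reps)) {
    for (ax in 1:3) {
      n <- d[ax]
      if (n < 3L) next
      lo <- c(1L, seq_len(n - 1L))
      hi <- c(seq(2L, n), n)
      a <- switch(ax,
        (a[lo, , , drop = FALSE] + a + a[hi, , , drop = FALSE]) / 3,
        (a[, lo, , drop = FALSE] + a + a[, hi, , drop = FALSE]) / 3,
        (a[, , lo, drop = FALSE] + a + a[, , hi, drop = FALSE]) / 3)
    }
  }
  a
}

#' Generate a synthetic glenoid CT volume with known ground truth
#'
#' Builds a glenoid-like voxel phantom — a capped elliptical cylinder with a
#' cortical shell and a trabecular interior whose bone/marrow texture is
#' assigned by thresholding a smooth random field to hit the requested
#' bone volume fraction exactly (in voxel counts) — plus homogeneous
#' air/fat/muscle reference blobs for calibration. Voxel grayscales are the
#' intrinsic scanner response to the noiseless BMD field, distorted by the
#' scanner gain/offset and additive Gaussian noise.
#'
#' The returned ground truth contains the noiseless BMD field, logical masks
#' for every structure, analytically placed anatomical landmarks, and the
#' achieved trabecular bone fraction, so downstream calibration, VOI
#' geometry and BV/TV estimates can be checked against exact truth.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `glenoid_phantom` with elements `ct` (a
#'   [ct_volume()]) and `truth` (list: `bmd` a [bmd_volume()], `masks`,
#'   `landmarks`, `axis`, `bone_fraction_achieved`, `n_bone`,
#'   `n_trabecular`, `width_mm`, `vault_depth_mm`, `spec`).
#' @examples
#' ph <- generate_phantom_ct(phantom_spec(seed = 7))
#' ph$truth$bone_fraction_achieved
#' @export
generate_phantom_ct <- function(spec) {
  spec <- validate_phantom_spec(unclass(spec))
  set.seed(spec$seed)
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  x <- (seq_len(d[1L]) - 1) * sp
  y <- (seq_len(d[2L]) - 1) * sp
  z <- (seq_len(d[3L]) - 1) * sp
  cy <- (d[2L] - 1) * sp / 2
  cz <- (d[3L] - 1) * sp / 2
  a <- spec$glenoid_width_mm / 2    # y semi-axis
  b <- spec$glenoid_height_mm / 2   # z semi-axis
  x0 <- spec$articular_offset_mm
  x1 <- x0 + spec$vault_depth_mm
  tc <- spec$cortical_thickness_vox * sp

  # sizing checks: glenoid inside the grid with >= 1 voxel margin,
  # interior non-degenerate
  if (cy - a < sp || cz - b < sp || x0 < 0 || x1 > max(x) ||
      a - tc <= 0 || b - tc <= 0 || x1 - x0 <= 2 * tc)
    stop("grid too small for the requested glenoid geometry", call. = FALSE)

  in_x <- x >= x0 & x <= x1
  ell_out <- outer(((y - cy) / a)^2, ((z - cz) / b)^2, "+") <= 1
  glenoid <- outer(in_x, ell_out) > 0

  in_x_int <- x >= x0 + tc & x <= x1 - tc
  ell_int <- outer(((y - cy) / (a - tc))^2, ((z - cz) / (b - tc))^2,
                   "+") <= 1
  trabecular <- outer(in_x_int, ell_int) > 0

  # reference-tissue blobs: three 6-voxel cubes medial to the vault
  bx <- (d[1L] - 9L):(d[1L] - 4L)
  if (min(bx) * sp <= x1)
    stop("grid too small to place reference blobs medial to the glenoid",
         call. = FALSE)
  ystarts <- round(c(0.08, 0.42, 0.76) * (d[2L] - 1L)) + 1L
  zstart <- round(0.08 * (d[3L] - 1L)) + 1L
  if (any(ystarts + 5L > d[2L]) || zstart + 5L > d[3L] ||
      any(diff(ystarts) < 6L))
    stop("grid too small to place reference blobs", call. = FALSE)
  blob_mask <- function(ys) {
    m <- array(FALSE, d)
    m[bx, ys:(ys + 5L), zstart:(zstart + 5L)] <- TRUE
    m
  }
  m_air <- blob_mask(ystarts[1L])
  m_fat <- blob_mask(ystarts[2L])
  m_muscle <- blob_mask(ystarts[3L])

  # trabecular texture: top-k voxels of a smooth random field are bone
  n_int <- sum(trabecular)
  field <- smooth3d_box(array(stats::rnorm(prod(d)), d))
  int_idx <- which(trabecular)
  k <- max(1L, round(spec$bone_fraction * n_int))
  sel <- order(field[int_idx], decreasing = TRUE)[seq_len(k)]
  bone_idx <- int_idx[sel]
  marrow_idx <- setdiff(int_idx, bone_idx)

  bmd <- array(BMD_ANCHORS[["air"]], d)
  bmd[glenoid] <- spec$cortical_bmd
  bmd[bone_idx] <- stats::rnorm(k, spec$trabecular_bmd_mean,
                                spec$trabecular_bmd_sd)
  if (length(marrow_idx))
    bmd[marrow_idx] <- stats::rnorm(length(marrow_idx), spec$marrow_bmd_mean,
                                    spec$marrow_bmd_sd)
  bone <- array(FALSE, d)
  bone[bone_idx] <- TRUE

  if (!is.null(spec$necrotic_pocket)) {
    np <- spec$necrotic_pocket
    r2 <- outer(outer((x - np$center_mm[1L])^2, (y - np$center_mm[2L])^2,
                      "+"), (z - np$center_mm[3L])^2, "+")
    pocket <- r2 <= np$radius_mm^2 & trabecular
    bmd[pocket] <- np$bmd
    bone <- bone & !pocket
  }

  bmd[m_air] <- BMD_ANCHORS[["air"]]
  bmd[m_fat] <- BMD_ANCHORS[["fat"]]
  bmd[m_muscle] <- BMD_ANCHORS[["muscle"]]

  gray <- spec$scanner_gain *
    bmd_to_grayscale(bmd, spec$reference_tissue_grayscale) +
    spec$scanner_offset
  if (spec$noise_sd > 0)
    gray <- gray + stats::rnorm(prod(d), 0, spec$noise_sd)
  dim(gray) <- d

  lm <- glenoid_landmarks(
    glenoid_center = c(x0, cy, cz),
    spine_root = c(x1 + 10, cy, cz),
    inferior_rim = c(x0, cy, cz - b),
    clock3 = c(x0, cy - a, cz),
    clock9 = c(x0, cy + a, cz),
    articular_cortex_level = 0,
    medial_cortex_level = spec$vault_depth_mm)

  structure(list(
    ct = ct_volume(gray, spacing_mm = sp),
    truth = list(
      bmd = bmd_volume(bmd, spacing_mm = sp),
      masks = list(glenoid = glenoid, trabecular = trabecular, bone = bone,
                   air = m_air, fat = m_fat, muscle = m_muscle),
      landmarks = lm,
      axis = c(1, 0, 0),
      bone_fraction_achieved = sum(bone) / n_int,
      n_bone = sum(bone), n_trabecular = n_int,
      width_mm = spec$glenoid_width_mm,
      vault_depth_mm = spec$vault_depth_mm,
      spec = spec)),
    class = "glenoid_phantom")
}

#' Extract reference-tissue calibration samples from a phantom
#'
#' Computes the mean observed grayscale over the phantom's air, fat and
#' muscle blob masks — the samples a user would obtain by placing reference
#' regions on a clinical scan.
#'
#' @param phantom A `glenoid_phantom` from [generate_phantom_ct()].
#' @return A data.frame with columns `tissue`, `mean_grayscale`,
#'   `voxel_count` suitable for [fit_calibration()].
#' @export
reference_samples <- function(phantom) {
  stopifnot(inherits(phantom, "glenoid_phantom"))
  g <- phantom$ct$values
  m <- phantom$truth$masks
  data.frame(
    tissue = c("air", "fat", "muscle"),
    mean_grayscale = c(mean(g[m$air]), mean(g[m$fat]), mean(g[m$muscle])),
    voxel_count = c(sum(m$air), sum(m$fat), sum(m$muscle)),
    stringsAsFactors = FALSE)
}
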