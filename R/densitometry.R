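# Patient-specific CT densitometry: grayscale -> BMD calibration and
# density / bone-volume-fraction extraction inside voxel masks.

#' Fit a patient-specific grayscale-to-BMD calibration
#'
#' Internal (phantomless) calibration for clinical CT: mean grayscales
#' sampled in air, subcutaneous fat and muscle are pinned to fixed
#' density-equivalent anchors of -840, -80 and +30 mgHA/cm^3 respectively,
#' and grayscale is mapped to BMD by linear interpolation between adjacent
#' anchors. Beyond the outer anchors the terminal segment slopes are
#' continued, so bone (well above the muscle grayscale) is extrapolated on
#' the fat-muscle slope. Because the map is refitted from each scan's own
#' reference samples, any affine scanner gain/offset cancels exactly.
#'
#' @param samples data.frame with columns `tissue` ("air", "fat", "muscle",
#'   exactly one row each), `mean_grayscale`, and optionally `voxel_count`.
#'   Grayscales must be strictly increasing air < fat < muscle.
#' @return An object of class `calibration_model`.
#' @examples
#' m <- fit_calibration(data.frame(tissue = c("air", "fat", "muscle"),
#'                                 mean_grayscale = c(-1000, -100, 40)))
#' predict(m, c(-1000, -100, 40))   # -840 -80 30
#' @export
fit_calibration <- function(samples) {
  if (!is.data.frame(samples) ||
      !all(c("tissue", "mean_grayscale") %in% names(samples)))
    stop("`samples` must have columns tissue and mean_grayscale",
         call. = FALSE)
  tissues <- c("air", "fat", "muscle")
  if (!setequal(samples$tissue, tissues) || nrow(samples) != 3L)
    stop("need exactly one sample for each of air, fat, muscle",
         call. = FALSE)
  if ("voxel_count" %in% names(samples) && any(samples$voxel_count <= 0))
    stop("voxel counts must be positive", call. = FALSE)
  g <- samples$mean_grayscale[match(tissues, samples$tissue)]
  if (any(!is.finite(g)) || !(g[1L] < g[2L] && g[2L] < g[3L]))
    stop("reference grayscales must be finite and increase air < fat < muscle",
         call. = FALSE)
  structure(list(anchors = data.frame(tissue = tissues, grayscale = g,
                                      bmd = unname(BMD_ANCHORS[tissues])),
                 extrapolation = "terminal-slopes"),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> grayscale -> BMD (mgHA/cm^3)\n")
  print(x$anchors, row.names = FALSE)
  invisible(x)
}

#' Evaluate a calibration model at grayscale values
#'
#' @param object A `calibration_model`.
#' @param newdata Numeric vector (or array) of grayscale values.
#' @param ... Unused.
#' @return BMD values (mgHA/cm^3), same shape as `newdata`.
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  a <- object$anchors
  out <- piecewise_two_segment(newdata, x_anchor = a$grayscale,
                               y_anchor = a$bmd)
  if (!is.null(dim(newdata))) dim(out) <- dim(newdata)
  out
}

#' Convert a CT grayscale volume to BMD
#'
#' Applies the fitted piecewise-linear calibration voxel-wise. The map is a
#' total, monotone non-decreasing function, so every grayscale value gets a
#' density.
#'
#' @param vol A [ct_volume()].
#' @param model A `calibration_model` from [fit_calibration()].
#' @return A [bmd_volume()] on the same grid.
#' @export
apply_calibration <- function(vol, model) {
  stopifnot(inherits(vol, "ct_volume"), inherits(model, "calibration_model"))
  bmd_volume(predict(model, vol$values), spacing_mm = vol$spacing_mm,
             origin = vol$origin)
}

#' Bone volume fraction (BV/TV) by voxel counting
#'
#' The fraction of voxels inside a mask whose BMD is at or above a global
#' segmentation threshold: BV/TV = #(BMD >= threshold) / #mask.
#'
#' @param vol A [bmd_volume()] (any `ct_volume` works; values are compared
#'   directly to `threshold`).
#' @param mask Logical array of the same shape; must select at least one
#'   voxel.
#' @param threshold Global bone segmentation threshold in mgHA/cm^3
#'   (default 100).
#' @return A fraction in \[0, 1\].
#' @export
compute_bvtv <- function(vol, mask, threshold = 100) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!is.logical(mask) || !identical(dim(mask), dim(vol$values)))
    stop("`mask` must be a logical array matching the volume", call. = FALSE)
  n <- sum(mask)
  if (n == 0L) stop("mask selects no voxels", call. = FALSE)
  sum(vol$values[mask] >= threshold) / n
}

#' Density metrics inside a cylindrical VOI
#'
#' Rasterizes the cylinder on the volume grid and reports mean and SD of
#' BMD plus BV/TV over the enclosed voxels.
#'
#' @param vol A [bmd_volume()].
#' @param voi A [cylinder_voi()] or a precomputed logical mask.
#' @param threshold Bone segmentation threshold (mgHA/cm^3) for BV/TV.
#' @param voi_name Label recorded in the output.
#' @return A one-row data.frame of class `density_metrics`: `voi_name`,
#'   `bmd_mean`, `bmd_sd`, `bvtv`, `voxel_count`.
#' @export
compute_voi_metrics <- function(vol, voi, threshold = 100,
                                voi_name = "voi") {
  stopifnot(inherits(vol, "ct_volume"))
  mask <- if (is.logical(voi)) voi else rasterize_voi(voi, vol)
  if (!identical(dim(mask), dim(vol$values)))
    stop("mask shape does not match volume", call. = FALSE)
  if (!any(mask)) stop("VOI does not intersect the volume", call. = FALSE)
  v <- vol$values[mask]
  out <- data.frame(voi_name = voi_name, bmd_mean = mean(v),
                    bmd_sd = stats::sd(v),
                    bvtv = compute_bvtv(vol, mask, threshold),
                    voxel_count = length(v), stringsAsFactors = FALSE)
  class(out) <- c("density_metrics", class(out))
  out
}
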