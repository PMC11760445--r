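#' Voxel volume containers
#'
#' A `ct_volume` holds a 3-D grayscale array together with its voxel spacing
#' (mm) and world-space origin; a `bmd_volume` is the same grid after
#' calibration to bone mineral density (mgHA/cm^3). The world coordinate of
#' the centre of the voxel with 0-based index `(i, j, k)` is
#' `origin + c(i, j, k) * spacing_mm`.
#'
#' @param values 3-D numeric array of voxel values.
#' @param spacing_mm Voxel edge lengths in mm; a scalar (isotropic) or a
#'   length-3 vector, all strictly positive.
#' @param origin World coordinates (mm) of the centre of voxel (0, 0, 0).
#' @return An object of class `ct_volume` (or `bmd_volume`).
#' @export
ct_volume <- function(values, spacing_mm = 0.6, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L || length(values) == 0L)
    stop("`values` must be a non-empty 3-D array", call. = FALSE)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 1 or 3 strictly positive values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite 3-vector", call. = FALSE)
  structure(
    list(values = values, spacing_mm = as.numeric(spacing_mm),
         origin = as.numeric(origin)),
    class = "ct_volume"
  )
}

#' @rdname ct_volume
#' @export
bmd_volume <- function(values, spacing_mm = 0.6, origin = c(0, 0, 0)) {
  vol <- ct_volume(values, spacing_mm, origin)
  class(vol) <- c("bmd_volume", "ct_volume")
  vol
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              class(x)[1L], d[1L], d[2L], d[3L],
              paste(signif(x$spacing_mm, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  value range [%.1f, %.1f]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' World coordinates of all voxel centres along one axis
#' @noRd
voxel_axis_mm <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing_mm[axis]
}

#' Check that two volumes share a grid
#' @noRd
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$spacing_mm, b$spacing_mm)) &&
    isTRUE(all.equal(a$origin, b$origin))
}
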