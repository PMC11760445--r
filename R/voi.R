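# Anatomical volume-of-interest geometry: the scapular axis, the coaxial
# glenoid-vault and subchondral cylinders, and their voxel rasterization.

#' Glenoid landmark set
#'
#' Named anatomical points (world mm) and two scalar levels along the
#' scapular axis that fully determine the cylindrical VOIs: the glenoid
#' centre and spine root define the axis; the 3 and 9 o'clock points set
#' the cylinder diameter; the articular and medial cortex levels (signed mm
#' along the axis from the glenoid centre, increasing medially) bound the
#' glenoid vault.
#'
#' @param glenoid_center,spine_root,inferior_rim,clock3,clock9 3-vectors,
#'   world mm.
#' @param articular_cortex_level,medial_cortex_level Scalars, mm along the
#'   axis from `glenoid_center`; the medial level must be the larger.
#' @return A list of class `glenoid_landmarks`.
#' @export
glenoid_landmarks <- function(glenoid_center, spine_root, inferior_rim,
                              clock3, clock9,
                              articular_cortex_level = 0,
                              medial_cortex_level) {
  pts <- list(glenoid_center = glenoid_center, spine_root = spine_root,
              inferior_rim = inferior_rim, clock3 = clock3, clock9 = clock9)
  for (nm in names(pts))
    if (length(pts[[nm]]) != 3L || any(!is.finite(pts[[nm]])))
      stop(sprintf("`%s` must be a finite 3-vector", nm), call. = FALSE)
  if (isTRUE(all.equal(clock3, clock9)))
    stop("3 and 9 o'clock points must differ", call. = FALSE)
  if (isTRUE(all.equal(spine_root, glenoid_center)))
    stop("spine root and glenoid centre must differ", call. = FALSE)
  if (!(medial_cortex_level > articular_cortex_level))
    stop("medial cortex level must lie medial to the articular level",
         call. = FALSE)
  structure(c(pts, list(articular_cortex_level = articular_cortex_level,
                        medial_cortex_level = medial_cortex_level)),
            class = "glenoid_landmarks")
}

#' Scapular axis from landmarks
#'
#' The axis runs through the glenoid centre and the root of the scapular
#' spine, anchored at the glenoid centre and oriented laterally-to-medially
#' (towards the spine root).
#'
#' @param lm A [glenoid_landmarks()].
#' @return List with `point` (the glenoid centre) and `axis` (unit
#'   3-vector).
#' @export
derive_scapular_axis <- function(lm) {
  stopifnot(inherits(lm, "glenoid_landmarks"))
  v <- lm$spine_root - lm$glenoid_center
  n <- sqrt(sum(v^2))
  if (n < sqrt(.Machine$double.eps))
    stop("degenerate geometry: spine root coincides with glenoid centre",
         call. = FALSE)
  list(point = lm$glenoid_center, axis = v / n)
}

#' Cylinder diameter: 50% of the 3-to-9 o'clock glenoid distance
#'
#' @param lm A [glenoid_landmarks()].
#' @return Diameter in mm.
#' @export
cylinder_diameter <- function(lm) {
  stopifnot(inherits(lm, "glenoid_landmarks"))
  d <- sqrt(sum((lm$clock3 - lm$clock9)^2))
  if (d <= 0) stop("zero 3-9 o'clock distance", call. = FALSE)
  0.5 * d
}

#' Cylindrical volume of interest
#'
#' A finite cylinder in world space: `base_point` on the axis at the
#' articular surface, unit `axis` oriented lateral-to-medial, covering the
#' half-open axial interval `[start_offset_mm, start_offset_mm + depth_mm)`
#' within radius `diameter_mm / 2`.
#'
#' @param base_point 3-vector, world mm.
#' @param axis 3-vector; normalized internally, must be non-zero.
#' @param diameter_mm,depth_mm Strictly positive extents.
#' @param start_offset_mm Axial start relative to `base_point` (>= 0).
#' @param name Optional label.
#' @return A list of class `cylinder_voi`.
#' @export
cylinder_voi <- function(base_point, axis, diameter_mm, depth_mm,
                         start_offset_mm = 0, name = "cylinder") {
  n <- sqrt(sum(axis^2))
  if (n < sqrt(.Machine$double.eps))
    stop("cylinder axis must be non-zero", call. = FALSE)
  if (diameter_mm <= 0 || depth_mm <= 0)
    stop("diameter and depth must be > 0", call. = FALSE)
  if (start_offset_mm < 0) stop("start offset must be >= 0", call. = FALSE)
  structure(list(base_point = as.numeric(base_point), axis = axis / n,
                 diameter_mm = diameter_mm, depth_mm = depth_mm,
                 start_offset_mm = start_offset_mm, name = name),
            class = "cylinder_voi")
}

#' @export
print.cylinder_voi <- function(x, ...) {
  cat(sprintf(
    "<cylinder_voi> '%s': d=%.1f mm, depth=%.1f mm, start=%.1f mm\n",
    x$name, x$diameter_mm, x$depth_mm, x$start_offset_mm))
  invisible(x)
}

#' Construct the glenoid-vault cylinder
#'
#' Coaxial with the scapular axis, starting at the articular surface and
#' reaching until one endpoint touches the medial cortex, i.e. depth =
#' medial cortex level - articular cortex level. Diameter follows the 50%
#' rule of [cylinder_diameter()].
#'
#' @param lm A [glenoid_landmarks()].
#' @param axis Optional axis (from [derive_scapular_axis()]); derived from
#'   the landmarks when omitted. Must point medially (towards the spine
#'   root).
#' @return A [cylinder_voi()] named `"glenoid_vault"`.
#' @export
construct_vault_cylinder <- function(lm, axis = NULL) {
  stopifnot(inherits(lm, "glenoid_landmarks"))
  ax <- derive_scapular_axis(lm)
  if (!is.null(axis)) {
    if (sum(axis * ax$axis) <= 0)
      stop("axis must be oriented lateral -> medial (towards the spine root)",
           call. = FALSE)
    ax$axis <- axis / sqrt(sum(axis^2))
  }
  depth <- lm$medial_cortex_level - lm$articular_cortex_level
  if (depth <= 0) stop("non-positive vault depth", call. = FALSE)
  base <- lm$glenoid_center + lm$articular_cortex_level * ax$axis
  cylinder_voi(base, ax$axis, diameter_mm = cylinder_diameter(lm),
               depth_mm = depth, start_offset_mm = 0,
               name = "glenoid_vault")
}

#' Construct the subchondral cylinder from the vault cylinder
#'
#' Same axis and diameter as the vault cylinder; depth is one-third of the
#' vault depth; the start is shifted medially past the articulating cortex
#' and any necrotic subchondral layer by `necrosis_offset_mm`.
#'
#' @param vault The vault [cylinder_voi()].
#' @param necrosis_offset_mm Axial offset (mm, >= 0) skipping the articular
#'   cortex and necrotic tissue; default 2.
#' @return A [cylinder_voi()] named `"subchondral"`.
#' @export
construct_subchondral_cylinder <- function(vault, necrosis_offset_mm = 2) {
  stopifnot(inherits(vault, "cylinder_voi"))
  if (necrosis_offset_mm < 0)
    stop("necrosis offset must be >= 0", call. = FALSE)
  depth <- vault$depth_mm / 3
  start <- vault$start_offset_mm + necrosis_offset_mm
  if (start + depth > vault$start_offset_mm + vault$depth_mm)
    stop("subchondral cylinder would extend past the medial cortex",
         call. = FALSE)
  cylinder_voi(vault$base_point, vault$axis, diameter_mm = vault$diameter_mm,
               depth_mm = depth, start_offset_mm = start,
               name = "subchondral")
}

#' Rasterize a cylinder VOI to a voxel mask
#'
#' A voxel belongs to the mask iff its centre lies inside the finite
#' cylinder (voxel-centre-in-solid rule; no partial volumes), matching the
#' pixel-counting convention of the density metrics.
#'
#' @param voi A [cylinder_voi()].
#' @param grid A [ct_volume()] (only its geometry is used).
#' @return Logical array with the grid's dimensions.
#' @export
rasterize_voi <- function(voi, grid) {
  stopifnot(inherits(voi, "cylinder_voi"), inherits(grid, "ct_volume"))
  d <- dim(grid$values)
  xs <- voxel_axis_mm(grid, 1L) - voi$base_point[1L]
  ys <- voxel_axis_mm(grid, 2L) - voi$base_point[2L]
  zs <- voxel_axis_mm(grid, 3L) - voi$base_point[3L]
  u <- voi$axis
  # axial coordinate t = p . u via separable outer sums
  t_ax <- outer(outer(xs * u[1L], ys * u[2L], "+"), zs * u[3L], "+")
  # squared radial distance = |p|^2 - t^2
  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+") - t_ax^2
  mask <- t_ax >= voi$start_offset_mm &
    t_ax < voi$start_offset_mm + voi$depth_mm &
    r2 <= (voi$diameter_mm / 2)^2
  if (!any(mask))
    stop("VOI does not intersect the volume grid", call. = FALSE)
  mask
}
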