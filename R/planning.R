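# Baseplate planning geometry: wedge augment lateralization, reaming
# medialization, and the wedge-to-bone contact-fraction check.

#' Lateral offset produced by a full-wedge augment
#'
#' A full wedge of angle `theta` under a circular baseplate of diameter `D`
#' raises the far rim by `(D / 2) * tan(theta)` relative to the hinge edge;
#' this rim height is the additional lateral offset of the centre of
#' rotation. For the 24 mm baseplate this gives 2.1 mm at 10 degrees and
#' 4.4 mm at 20 degrees.
#'
#' @param correction_deg Wedge (inclination correction) angle in degrees,
#'   in \[0, 90).
#' @param baseplate_diameter_mm Baseplate diameter (default 24).
#' @return Lateral offset in mm, rounded to 0.1 mm.
#' @examples
#' wedge_lateral_offset(10)  # 2.1
#' wedge_lateral_offset(20)  # 4.4
#' @export
wedge_lateral_offset <- function(correction_deg, baseplate_diameter_mm = 24) {
  if (any(correction_deg < 0) || any(correction_deg >= 90))
    stop("correction angle must lie in [0, 90) degrees", call. = FALSE)
  if (any(baseplate_diameter_mm <= 0))
    stop("baseplate diameter must be > 0", call. = FALSE)
  round((baseplate_diameter_mm / 2) * tan(correction_deg * pi / 180), 1)
}

#' Medialization of the centre of rotation by corrective reaming
#'
#' Achieving the same angular correction by reaming instead of augmenting
#' removes the same wedge of bone from the glenoid, so the centre of
#' rotation moves medially by the magnitude of [wedge_lateral_offset()].
#' Reported as a negative lateral offset.
#'
#' @inheritParams wedge_lateral_offset
#' @return Signed offset in mm (negative = medial), rounded to 0.1 mm.
#' @export
reaming_medialization <- function(correction_deg, baseplate_diameter_mm = 24) {
  -wedge_lateral_offset(correction_deg, baseplate_diameter_mm)
}

#' Fraction of the baseplate footprint in contact with prepared bone
#'
#' Seats a wedge-backed circular baseplate on a prepared bone surface and
#' reports the fraction of footprint sample points whose residual gap to
#' the wedge underside is within a contact tolerance. The wedge is lowered
#' rigidly along its axis until it first touches the surface (minimum gap
#' zero); tilt/rock optimization beyond the axial seating is handled by
#' [optimize_wedge_rotation()] through the wedge rotation angle.
#'
#' @param surface A function `f(x, y)` returning the prepared bone height
#'   (mm) over footprint coordinates, or a matrix of heights sampled on the
#'   grid defined by `n_grid` over the footprint bounding square. `NA`
#'   heights mark points off the prepared surface.
#' @param diameter_mm Footprint (baseplate) diameter, default 24.
#' @param wedge_angle_deg Wedge angle (deg).
#' @param wedge_rotation_deg Rotation of the wedge's high side about the
#'   implant axis (deg; 0 = high side towards +x).
#' @param contact_tol_mm Maximum residual gap counted as contact
#'   (default 0.1 mm).
#' @param n_grid Sample points per axis across the footprint (default 41).
#' @return Fraction in \[0, 1\] of footprint samples in contact.
#' @export
contact_fraction <- function(surface, diameter_mm = 24, wedge_angle_deg = 0,
                             wedge_rotation_deg = 0, contact_tol_mm = 0.1,
                             n_grid = 41L) {
  r <- diameter_mm / 2
  xs <- seq(-r, r, length.out = n_grid)
  pts <- expand.grid(x = xs, y = xs)
  inside <- pts$x^2 + pts$y^2 <= r^2
  pts <- pts[inside, ]
  s <- if (is.function(surface)) {
    surface(pts$x, pts$y)
  } else if (is.matrix(surface)) {
    if (!identical(dim(surface), c(n_grid, n_grid)))
      stop("surface matrix must be n_grid x n_grid over the footprint",
           call. = FALSE)
    surface[cbind(match(pts$x, xs), match(pts$y, xs))]
  } else stop("`surface` must be a function or a matrix", call. = FALSE)
  ok <- is.finite(s)
  if (!any(ok))
    stop("footprint lies entirely off the prepared surface", call. = FALSE)
  # wedge underside height over the footprint, high side along the rotated
  # +x direction, hinge at the opposite rim
  phi <- wedge_rotation_deg * pi / 180
  along <- pts$x * cos(phi) + pts$y * sin(phi)
  w <- (along + r) * tan(wedge_angle_deg * pi / 180)
  gap <- (w - s)[ok]
  gap <- gap - min(gap)   # rigid axial seating: touch at min gap
  mean(gap <= contact_tol_mm)
}

#' Find the smallest wedge rotation reaching the contact threshold
#'
#' Grid search over whole-degree wedge rotations in \[-180, 180), returning
#' the smallest-magnitude rotation whose contact fraction meets
#' `threshold` (ties broken towards the positive rotation). If no rotation
#' reaches the threshold the plan is flagged as not achievable.
#'
#' @inheritParams contact_fraction
#' @param threshold Minimum acceptable contact fraction (default 0.8).
#' @param step_deg Search grid step (default 1 degree).
#' @return List: `rotation_deg` (NA if not achievable), `contact_fraction`,
#'   `achievable` (logical).
#' @export
optimize_wedge_rotation <- function(surface, diameter_mm = 24,
                                    wedge_angle_deg = 0,
                                    contact_tol_mm = 0.1,
                                    threshold = 0.8, step_deg = 1,
                                    n_grid = 41L) {
  rotations <- seq(-180, 180 - step_deg, by = step_deg)
  fracs <- vapply(rotations, function(rot)
    contact_fraction(surface, diameter_mm, wedge_angle_deg, rot,
                     contact_tol_mm, n_grid), numeric(1L))
  hit <- which(fracs >= threshold)
  if (!length(hit))
    return(list(rotation_deg = NA_real_,
                contact_fraction = max(fracs), achievable = FALSE))
  # smallest |rotation|; prefer the positive one on magnitude ties
  best <- hit[order(abs(rotations[hit]), -sign(rotations[hit]))][1L]
  list(rotation_deg = rotations[best], contact_fraction = fracs[best],
       achievable = TRUE)
}

#' Assemble a baseplate plan
#'
#' Records the placement rules and correction geometry for one specimen:
#' a circular baseplate positioned 3 mm superior to the inferior glenoid
#' rim, targeting 0 degrees inclination (RSA angle) and 5 degrees of
#' retroversion, with the correction delivered by reaming (reference),
#' a metal augment (MA) or a bone-graft wedge (BIO). Lateral offset is the
#' wedge rim height for augments and the (negative) reaming medialization
#' for the reference method.
#'
#' @param method `"ream"`, `"MA"` or `"BIO"`.
#' @param correction_deg 0, 10 or 20 degrees.
#' @param baseplate_diameter_mm Default 24.
#' @param inferior_rim_offset_mm Default 3.
#' @param target_inclination_deg Default 0 (the target RSA angle).
#' @param target_retroversion_deg Default 5.
#' @param wedge_rotation_deg Optional wedge rotation from
#'   [optimize_wedge_rotation()].
#' @param contact_fraction Optional achieved contact fraction.
#' @return A list of class `baseplate_plan`.
#' @export
baseplate_plan <- function(method = c("ream", "MA", "BIO"),
                           correction_deg = 0,
                           baseplate_diameter_mm = 24,
                           inferior_rim_offset_mm = 3,
                           target_inclination_deg = 0,
                           target_retroversion_deg = 5,
                           wedge_rotation_deg = NA_real_,
                           contact_fraction = NA_real_) {
  method <- match.arg(method)
  if (!correction_deg %in% c(0, 10, 20))
    stop("correction must be 0, 10 or 20 degrees", call. = FALSE)
  if (method == "ream" && correction_deg != 0) {
    # reaming delivers the correction by removing bone; still a valid plan
    lateral <- reaming_medialization(correction_deg, baseplate_diameter_mm)
  } else if (method == "ream") {
    lateral <- 0
  } else {
    lateral <- wedge_lateral_offset(correction_deg, baseplate_diameter_mm)
  }
  if (!is.na(contact_fraction) &&
      (contact_fraction < 0 || contact_fraction > 1))
    stop("contact fraction must lie in [0, 1]", call. = FALSE)
  structure(list(method = method, correction_deg = correction_deg,
                 baseplate_diameter_mm = baseplate_diameter_mm,
                 inferior_rim_offset_mm = inferior_rim_offset_mm,
                 target_inclination_deg = target_inclination_deg,
                 target_retroversion_deg = target_retroversion_deg,
                 wedge_rotation_deg = wedge_rotation_deg,
                 lateral_offset_mm = lateral,
                 contact_fraction = contact_fraction),
            class = "baseplate_plan")
}

#' @export
print.baseplate_plan <- function(x, ...) {
  cat(sprintf(
    "<baseplate_plan> %s, %d deg correction: %d mm baseplate, %g mm above inferior rim\n",
    x$method, x$correction_deg, x$baseplate_diameter_mm,
    x$inferior_rim_offset_mm))
  cat(sprintf("  targets: %g deg inclination, %g deg retroversion\n",
              x$target_inclination_deg, x$target_retroversion_deg))
  cat(sprintf("  lateral offset %.1f mm%s\n", x$lateral_offset_mm,
              if (!is.na(x$contact_fraction))
                sprintf(", contact %.0f%%", 100 * x$contact_fraction)
              else ""))
  invisible(x)
}
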