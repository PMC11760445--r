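#' Specification for a synthetic glenoid CT phantom
#'
#' The phantom emulates a clinical shoulder CT cropped around the glenoid:
#' a capped elliptical cylinder of bone (cortical shell around a trabecular
#' interior) aligned with a "medial" x axis, plus three homogeneous
#' reference-tissue blobs (air, fat, muscle) used for patient-specific
#' densitometric calibration. All ground truth (noiseless BMD field, masks,
#' landmarks) is emitted analytically by [generate_phantom_ct()].
#'
#' @param grid_shape Voxel counts along x, y, z (default `c(64, 64, 64)`).
#' @param spacing_mm Isotropic voxel edge length in mm (default 0.6, the
#'   resolution of a standard clinical shoulder protocol).
#' @param trabecular_bmd_mean,trabecular_bmd_sd Mean and SD (mgHA/cm^3) of
#'   per-voxel BMD assigned to trabecular bone voxels.
#' @param marrow_bmd_mean,marrow_bmd_sd BMD distribution of intra-trabecular
#'   marrow voxels; centred near the fat anchor (-80 mgHA/cm^3).
#' @param cortical_bmd BMD of the cortical shell (mgHA/cm^3); must exceed
#'   `trabecular_bmd_mean`.
#' @param bone_fraction Target true BV/TV of the trabecular interior, in
#'   (0, 1]. Bone voxels are selected by thresholding a smooth random field
#'   so the achieved count matches `round(bone_fraction * n_interior)`.
#' @param glenoid_width_mm 3-to-9 o'clock articular width (ellipse diameter
#'   along y, mm).
#' @param glenoid_height_mm Superoinferior extent (ellipse diameter along z,
#'   mm).
#' @param vault_depth_mm Distance from the articular cortex to the medial
#'   cortex along the scapular axis (mm).
#' @param articular_offset_mm World x of the articular surface (mm).
#' @param cortical_thickness_vox Shell thickness in voxels (1-2 typical).
#' @param reference_tissue_grayscale Named scanner grayscales for pure
#'   air/fat/muscle, i.e. the intrinsic scanner response at the calibration
#'   anchor densities; must be strictly increasing.
#' @param scanner_gain,scanner_offset Affine distortion applied to the
#'   intrinsic grayscale, emulating inter-scan gain/offset drift.
#' @param noise_sd Grayscale noise SD added per voxel.
#' @param necrotic_pocket Optional `list(center_mm =, radius_mm =, bmd =)`
#'   sphere of low-density (necrotic) tissue carved into the interior.
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return A validated list of class `phantom_spec`.
#' @seealso [generate_phantom_ct()]
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing_mm = 0.6,
                         trabecular_bmd_mean = 350,
                         trabecular_bmd_sd = 40,
                         marrow_bmd_mean = -80,
                         marrow_bmd_sd = 20,
                         cortical_bmd = 800,
                         bone_fraction = 0.66,
                         glenoid_width_mm = 28,
                         glenoid_height_mm = 24,
                         vault_depth_mm = 24,
                         articular_offset_mm = 4.8,
                         cortical_thickness_vox = 2L,
                         reference_tissue_grayscale =
                           c(air = -1000, fat = -100, muscle = 40),
                         scanner_gain = 1,
                         scanner_offset = 0,
                         noise_sd = 10,
                         necrotic_pocket = NULL,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
               trabecular_bmd_mean = trabecular_bmd_mean,
               trabecular_bmd_sd = trabecular_bmd_sd,
               marrow_bmd_mean = marrow_bmd_mean,
               marrow_bmd_sd = marrow_bmd_sd,
               cortical_bmd = cortical_bmd, bone_fraction = bone_fraction,
               glenoid_width_mm = glenoid_width_mm,
               glenoid_height_mm = glenoid_height_mm,
               vault_depth_mm = vault_depth_mm,
               articular_offset_mm = articular_offset_mm,
               cortical_thickness_vox = as.integer(cortical_thickness_vox),
               reference_tissue_grayscale = reference_tissue_grayscale,
               scanner_gain = scanner_gain, scanner_offset = scanner_offset,
               noise_sd = noise_sd, necrotic_pocket = necrotic_pocket,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$grid_shape) == 3L)
  if (any(spec$grid_shape < 8L))
    stop("phantom grid must be at least 8 voxels per axis", call. = FALSE)
  if (!is.numeric(spec$spacing_mm) || spec$spacing_mm <= 0)
    stop("`spacing_mm` must be > 0", call. = FALSE)
  if (spec$bone_fraction <= 0 || spec$bone_fraction > 1)
    stop("`bone_fraction` must lie in (0, 1]", call. = FALSE)
  if (spec$cortical_bmd <= spec$trabecular_bmd_mean)
    stop("`cortical_bmd` must exceed `trabecular_bmd_mean`", call. = FALSE)
  g <- spec$reference_tissue_grayscale
  if (!all(c("air", "fat", "muscle") %in% names(g)))
    stop("reference grayscales must be named air, fat, muscle", call. = FALSE)
  if (!(g[["air"]] < g[["fat"]] && g[["fat"]] < g[["muscle"]]))
    stop("reference grayscales must increase air < fat < muscle",
         call. = FALSE)
  if (spec$scanner_gain <= 0) stop("`scanner_gain` must be > 0", call. = FALSE)
  if (spec$noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.null(spec$necrotic_pocket)) {
    np <- spec$necrotic_pocket
    stopifnot(length(np$center_mm) == 3L, np$radius_mm > 0,
              is.numeric(np$bmd))
  }
  structure(spec, class = "phantom_spec")
}

#' Specification for a synthetic rocking-horse bench recording
#'
#' Encodes the loading protocol of a biaxial rocking-horse primary-stability
#' test: constant compression with a sinusoidal superoinferior shear force,
#' optical marker tracking of the glenosphere, the glenoid rim and (for
#' bone-graft constructs) the graft. Defaults follow the ASTM F2028-style
#' protocol used throughout the package: 430 N compression, 350 N shear at
#' 1/6 Hz for 25 cycles, sampled at 5 Hz, with 10,000 abduction fatigue
#' cycles between the pre and post phases and 2.8 um optical accuracy.
#'
#' @param n_cycles Shear cycles recorded per phase (default 25).
#' @param shear_freq_hz Shear cycle frequency (default 1/6 Hz).
#' @param sample_hz Optical sampling rate (default 5 Hz); must give at least
#'   10 frames per shear cycle.
#' @param compression_n,shear_n Compressive and peak shear loads (N).
#' @param fatigue_cycles,abduction_range_deg Fatigue protocol between the
#'   phases (recorded as metadata; the articulation itself is not simulated).
#' @param elastic_amplitude_um Peak-to-peak relative glenosphere-vs-glenoid
#'   displacement per shear cycle in the pre phase (um).
#' @param post_added_um Elastic amplitude added after fatigue loading, so the
#'   post-phase amplitude is `elastic_amplitude_um + post_added_um`.
#' @param permanent_offset_um Constant (permanent migration) offset present
#'   in the post phase (um).
#' @param rot_amplitude_deg Rotational oscillation amplitude of the
#'   glenosphere per cycle (deg).
#' @param rot_post_added_deg Rotational amplitude added after fatigue.
#' @param graft_split Fraction of the total relative motion occurring at the
#'   implant-graft interface (bone-graft constructs only); `NULL` for
#'   constructs without a separately tracked graft. Default in
#'   [generate_cohort()] for BIO specimens is 0.53.
#' @param marker_noise_um Optical noise SD per coordinate (default 2.8 um).
#' @param seed Integer seed.
#' @return A validated list of class `bench_spec`.
#' @seealso [generate_marker_recording()]
#' @export
bench_spec <- function(n_cycles = 25L,
                       shear_freq_hz = 1 / 6,
                       sample_hz = 5,
                       compression_n = 430,
                       shear_n = 350,
                       fatigue_cycles = 10000L,
                       abduction_range_deg = c(45, 93),
                       elastic_amplitude_um = 60,
                       post_added_um = 20,
                       permanent_offset_um = 10,
                       rot_amplitude_deg = 0.2,
                       rot_post_added_deg = 0.05,
                       graft_split = NULL,
                       marker_noise_um = 2.8,
                       seed = 1L) {
  spec <- list(n_cycles = as.integer(n_cycles), shear_freq_hz = shear_freq_hz,
               sample_hz = sample_hz, compression_n = compression_n,
               shear_n = shear_n, fatigue_cycles = as.integer(fatigue_cycles),
               abduction_range_deg = abduction_range_deg,
               elastic_amplitude_um = elastic_amplitude_um,
               post_added_um = post_added_um,
               permanent_offset_um = permanent_offset_um,
               rot_amplitude_deg = rot_amplitude_deg,
               rot_post_added_deg = rot_post_added_deg,
               graft_split = graft_split,
               marker_noise_um = marker_noise_um, seed = as.integer(seed))
  validate_bench_spec(spec)
}

validate_bench_spec <- function(spec) {
  if (spec$n_cycles < 1L) stop("`n_cycles` must be >= 1", call. = FALSE)
  frames_per_cycle <- spec$sample_hz / spec$shear_freq_hz
  if (frames_per_cycle < 10)
    stop("sample_hz / shear_freq_hz must give >= 10 frames per cycle",
         call. = FALSE)
  amps <- c(spec$elastic_amplitude_um, spec$post_added_um,
            spec$permanent_offset_um, spec$rot_amplitude_deg,
            spec$rot_post_added_deg, spec$marker_noise_um)
  if (any(amps < 0)) stop("amplitudes and noise must be >= 0", call. = FALSE)
  if (!is.null(spec$graft_split) &&
      (spec$graft_split < 0 || spec$graft_split > 1))
    stop("`graft_split` must lie in [0, 1]", call. = FALSE)
  structure(spec, class = "bench_spec")
}

#' Specification for a synthetic specimen cohort
#'
#' Describes a five-group study design: a corrective-reaming reference group
#' and metal-augment (MA) / bone-graft (BIO) groups at 10 and 20 degrees of
#' inclination correction. Per-specimen subchondral density and total
#' (post-cyclic) micromotion are drawn per group; in the BIO groups the two
#' are drawn from a bivariate normal with correlation
#' `bio_density_micromotion_rho` (default -0.63), in the other groups they
#' are independent.
#'
#' Default group sizes are 10/5/5/5/5 (Reference/MA10/MA20/BIO10/BIO20) and
#' default subchondral BMD levels are 238 +/- 37 (Reference), 217 +/- 34
#' (MA) and 211 +/- 16 (BIO) mgHA/cm^3.
#'
#' @param n_per_group Named integer vector of group sizes; names must be
#'   `Reference`, `MA10`, `MA20`, `BIO10`, `BIO20`. Every group needs >= 2
#'   specimens for downstream statistics.
#' @param density_mean,density_sd Named per-group subchondral BMD
#'   distributions (mgHA/cm^3).
#' @param micromotion_mean,micromotion_sd Named per-group total micromotion
#'   distributions (um).
#' @param rotation_mean,rotation_sd Named per-group rotational displacement
#'   distributions (deg); the 20-degree groups default to larger spread.
#' @param bio_density_micromotion_rho Correlation between density and
#'   micromotion imposed in the BIO groups (default -0.63).
#' @param seed Master seed; per-specimen substreams are derived from it by
#'   fixed increments so cohort reproducibility does not depend on
#'   iteration order.
#' @return A validated list of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_per_group = c(Reference = 10L, MA10 = 5L, MA20 = 5L,
                                        BIO10 = 5L, BIO20 = 5L),
                        density_mean = c(Reference = 238, MA10 = 217,
                                         MA20 = 217, BIO10 = 211, BIO20 = 211),
                        density_sd = c(Reference = 37, MA10 = 34, MA20 = 34,
                                       BIO10 = 16, BIO20 = 16),
                        micromotion_mean = c(Reference = 60, MA10 = 70,
                                             MA20 = 75, BIO10 = 85, BIO20 = 95),
                        micromotion_sd = c(Reference = 12, MA10 = 14,
                                           MA20 = 16, BIO10 = 24, BIO20 = 28),
                        rotation_mean = c(Reference = 0.20, MA10 = 0.22,
                                          MA20 = 0.25, BIO10 = 0.24,
                                          BIO20 = 0.28),
                        rotation_sd = c(Reference = 0.04, MA10 = 0.05,
                                        MA20 = 0.09, BIO10 = 0.06,
                                        BIO20 = 0.10),
                        bio_density_micromotion_rho = -0.63,
                        seed = 1L) {
  spec <- list(n_per_group = n_per_group, density_mean = density_mean,
               density_sd = density_sd, micromotion_mean = micromotion_mean,
               micromotion_sd = micromotion_sd, rotation_mean = rotation_mean,
               rotation_sd = rotation_sd,
               bio_density_micromotion_rho = bio_density_micromotion_rho,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
}

cohort_group_names <- c("Reference", "MA10", "MA20", "BIO10", "BIO20")

validate_cohort_spec <- function(spec) {
  for (field in c("n_per_group", "density_mean", "density_sd",
                  "micromotion_mean", "micromotion_sd",
                  "rotation_mean", "rotation_sd")) {
    v <- spec[[field]]
    if (!all(cohort_group_names %in% names(v)))
      stop(sprintf("`%s` must be named for groups %s", field,
                   paste(cohort_group_names, collapse = ", ")), call. = FALSE)
  }
  if (any(spec$n_per_group[cohort_group_names] < 2L))
    stop("every group needs n >= 2 for downstream statistics", call. = FALSE)
  rho <- spec$bio_density_micromotion_rho
  if (abs(rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
  if (any(spec$density_sd < 0) || any(spec$micromotion_sd < 0) ||
      any(spec$rotation_sd < 0))
    stop("spread parameters must be >= 0", call. = FALSE)
  structure(spec, class = "cohort_spec")
}

#' Derive a deterministic per-specimen seed from a master seed
#'
#' Fixed-increment substreams keep each specimen's random draws independent
#' of cohort iteration order while staying inside 32-bit integer range.
#' @noRd
specimen_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 7919 * as.numeric(index)) %%
               .Machine$integer.max)
}
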