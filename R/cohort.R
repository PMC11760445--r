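# Synthetic specimen cohorts with group structure and an imposed
# density-micromotion correlation in the bone-graft groups.

#' Default implant-graft share of total motion for BIO constructs
#'
#' Fraction of the total relative glenosphere-vs-glenoid motion attributed
#' to the implant-graft interface in bone-graft constructs; the remainder
#' occurs at the graft-glenoid interface. Used as the generator default
#' wherever a BIO specimen is materialized.
#' @export
DEFAULT_GRAFT_SPLIT <- 0.53

#' Generate a synthetic study cohort
#'
#' Draws one specimen table for the five-group design (Reference, MA 10/20
#' degrees, BIO 10/20 degrees). Each specimen gets a subchondral density, a
#' total (post-cyclic) micromotion and a rotational displacement drawn from
#' its group's distributions. In the BIO groups density and micromotion are
#' drawn from a bivariate normal with correlation
#' `spec$bio_density_micromotion_rho`; in the MA and Reference groups they
#' are independent. Each specimen's draws come from a fixed-increment
#' substream of the master seed, so the table is reproducible specimen by
#' specimen.
#'
#' The table carries generator truth (the injected outcome values); use
#' [materialize_specimen()] to turn a row into a phantom plus pre/post
#' marker recordings and push it through the full measurement pipeline.
#'
#' @param spec A [cohort_spec()].
#' @return data.frame of class `specimen_cohort`: `specimen_id`, `group`
#'   (design cell), `group3` (Reference/MA/BIO), `method` (ream/MA/BIO),
#'   `correction_deg`, `density_subchondral`, `micromotion_um`,
#'   `rotation_deg`, `seed`.
#' @export
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(unclass(spec))
  groups <- rep(cohort_group_names,
                times = spec$n_per_group[cohort_group_names])
  n <- length(groups)
  rho <- spec$bio_density_micromotion_rho
  dens <- mic <- rot <- numeric(n)
  seeds <- integer(n)
  for (i in seq_len(n)) {
    g <- groups[i]
    seeds[i] <- specimen_seed(spec$seed, i)
    set.seed(seeds[i])
    z <- stats::rnorm(3L)
    dens[i] <- spec$density_mean[[g]] + spec$density_sd[[g]] * z[1L]
    r <- if (startsWith(g, "BIO")) rho else 0
    mic[i] <- spec$micromotion_mean[[g]] + spec$micromotion_sd[[g]] *
      (r * z[1L] + sqrt(1 - r^2) * z[2L])
    rot[i] <- spec$rotation_mean[[g]] + spec$rotation_sd[[g]] * z[3L]
  }
  correction <- integer(n)
  nonref <- groups != "Reference"
  correction[nonref] <- as.integer(sub("^[A-Z]+", "", groups[nonref]))
  out <- data.frame(
    specimen_id = sprintf("S%03d", seq_len(n)),
    group = groups,
    group3 = sub("[0-9]+$", "", groups),
    method = ifelse(nonref, sub("[0-9]+$", "", groups), "ream"),
    correction_deg = correction,
    density_subchondral = dens,
    micromotion_um = pmax(1, mic),
    rotation_deg = pmax(0.01, rot),
    seed = seeds,
    stringsAsFactors = FALSE)
  class(out) <- c("specimen_cohort", class(out))
  out
}

#' Materialize one cohort specimen as phantom + bench recordings
#'
#' Converts a [generate_cohort()] row into concrete synthetic inputs: a CT
#' phantom whose trabecular density reproduces the specimen's subchondral
#' BMD (with per-specimen scanner gain/offset jitter), and pre/post marker
#' recordings whose injected amplitudes reproduce the specimen's total
#' micromotion and rotation. BIO specimens get a separately tracked graft
#' carrying the configured interface split.
#'
#' @param row One-row data.frame (a cohort table row).
#' @param phantom_base,bench_base Template [phantom_spec()] /
#'   [bench_spec()] providing all non-specimen-specific settings.
#' @param graft_split_bio Implant-graft share of total motion for BIO
#'   specimens (default 0.53).
#' @return List with `phantom_spec`, `bench` (the per-specimen
#'   [bench_spec()]), `phantom`, `pre`, `post`.
#' @export
materialize_specimen <- function(row, phantom_base = phantom_spec(),
                                 bench_base = bench_spec(),
                                 graft_split_bio = DEFAULT_GRAFT_SPLIT) {
  stopifnot(nrow(row) == 1L)
  pb <- unclass(phantom_base)
  bb <- unclass(bench_base)

  # back out the trabecular mean giving the requested subchondral mean BMD
  bf <- pb$bone_fraction
  pb$trabecular_bmd_mean <-
    (row$density_subchondral - (1 - bf) * pb$marrow_bmd_mean) / bf
  pb$seed <- specimen_seed(row$seed, 10L)
  set.seed(specimen_seed(row$seed, 11L))
  pb$scanner_gain <- 1 + 0.05 * stats::rnorm(1L)
  pb$scanner_offset <- 20 * stats::rnorm(1L)

  bb$elastic_amplitude_um <- max(1, row$micromotion_um - bb$post_added_um)
  bb$rot_amplitude_deg <- max(0.005,
                              row$rotation_deg - bb$rot_post_added_deg)
  bb$graft_split <- if (row$method == "BIO") graft_split_bio else NULL
  bb$seed <- specimen_seed(row$seed, 12L)

  pspec <- validate_phantom_spec(pb)
  bspec <- validate_bench_spec(bb)
  list(phantom_spec = pspec, bench = bspec,
       phantom = generate_phantom_ct(pspec),
       pre = generate_marker_recording(bspec, "pre"),
       post = generate_marker_recording(bspec, "post"))
}
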