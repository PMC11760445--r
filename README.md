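# glenostab

Glenoid bone density and reverse shoulder arthroplasty (RSA) baseplate
stability analysis.

## What this package is for

Whether an RSA glenoid baseplate stays fixed long enough for bone to grow
into it depends on its primary (time-zero) mechanical stability, and that
stability interacts with the quality of the bone it is anchored in —
especially when the inclination of the glenoid is corrected with a bone
graft (BIO-RSA) or a metal augment (MA-RSA) instead of corrective reaming.
`glenostab` implements the full measurement chain used to study this
question, for biomechanics researchers and implant-planning engineers:

* **CT densitometry** — patient-specific (phantomless) calibration that
  maps scanner grayscale to bone mineral density by pinning air, fat and
  muscle reference samples to −840, −80 and +30 mgHA/cm³ and
  interpolating linearly; BMD statistics and pixel-counting bone volume
  fraction (BV/TV = #{voxels ≥ threshold} / #voxels) inside anatomical
  volumes of interest.
* **VOI geometry** — the scapular axis through the glenoid centre and
  spine root; coaxial glenoid-vault and subchondral cylinders with
  diameter = 50 % of the 3–9 o'clock width, vault depth to the medial
  cortex, subchondral depth = vault/3 starting past the articular cortex.
* **Augment planning** — full-wedge lateralization Δ = (D/2)·tan θ
  (2.1 / 4.4 mm at 10° / 20° on a 24 mm baseplate), reaming
  medialization, and a wedge-seating contact-fraction check with rotation
  optimization.
* **Micromotion analysis** — rigid-body (Kabsch) marker tracking of the
  glenosphere, glenoid rim and optional graft during rocking-horse shear
  loading; relative displacement and rotation series; mean per-cycle
  min-to-max ranges pre and post fatigue; interface partitioning for
  bone-graft constructs; the 150 µm osseointegration limit.
* **Statistics** — Shapiro–Wilk / Brown–Forsythe gating into one-way
  ANOVA + Holm–Šidák or Kruskal–Wallis + Dunn–Bonferroni, variability
  comparisons, per-group Pearson correlations, observed power, and report
  tables.
* **Synthetic data** — voxel phantoms with exact ground truth, bench
  recordings with known injected motion, and cohorts with an imposed
  density–micromotion correlation, so the entire pipeline is testable
  without cadaveric data.

See `vignettes/methods.Rmd` for the models, assumptions and design
decisions.

## Worked example

```r
library(glenostab)

# a synthetic glenoid CT with known ground truth
ph    <- generate_phantom_ct(phantom_spec(seed = 42))
model <- fit_calibration(reference_samples(ph))
model
#> <calibration_model> grayscale -> BMD (mgHA/cm^3)
#>  tissue  grayscale  bmd
#>     air -999.70250 -840
#>     fat  -99.76877  -80
#>  muscle   39.75451   30

bmd   <- apply_calibration(ph$ct, model)
vault <- construct_vault_cylinder(ph$truth$landmarks)
subch <- construct_subchondral_cylinder(vault, necrosis_offset_mm = 2)
rbind(compute_voi_metrics(bmd, subch, 100, "subchondral"),
      compute_voi_metrics(bmd, vault, 100, "glenoid_vault"))
#>        voi_name bmd_mean   bmd_sd      bvtv voxel_count
#> 1   subchondral 194.3273 210.5551 0.6363960        5616
#> 2 glenoid_vault 254.0201 269.3930 0.6727642       17712

baseplate_plan("MA", 20)
#> <baseplate_plan> MA, 20 deg correction: 24 mm baseplate, 3 mm above inferior rim
#>   targets: 0 deg inclination, 5 deg retroversion
#>   lateral offset 4.4 mm

# a pre/post rocking-horse bench test with 2.8 um optical noise
sp <- bench_spec(seed = 42)
stability_outcome(generate_marker_recording(sp, "pre"),
                  generate_marker_recording(sp, "post"))
#> <stability_outcome>
#>   micromotion (um): pre 61.0, post 79.1, delta 18.1
#>   rotation (deg): pre 0.243, post 0.290, delta 0.047
```

Reading the numbers: the fitted calibration reproduces the three density
anchors from the phantom's own reference regions; the subchondral cylinder
averages ~194 mgHA/cm³ with BV/TV 0.64 over 5616 voxels; a 20° metal
augment lateralizes the centre of rotation by 4.4 mm; and the bench run
measures 61 µm of cyclic micromotion before and 79 µm after fatigue
loading — well below the 150 µm limit held to impair osseointegration —
the 18 µm difference being the motion added by 10,000 abduction cycles.

A full synthetic study (cohort → densitometry → planning → micromotion →
statistics, with all report tables written to disk) is one call:

```r
run_pipeline(pipeline_config(seed = 1, out_dir = "study_out"))
```

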