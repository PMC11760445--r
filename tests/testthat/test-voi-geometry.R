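# Scapular axis, cylinder construction rules and voxel rasterization.

lm_fixture <- function(center = c(0, 0, 0), spine = c(30, 0, 0),
                       width = 28, vault = 30) {
  glenoid_landmarks(glenoid_center = center, spine_root = spine,
                    inferior_rim = center + c(0, 0, -width / 2),
                    clock3 = center + c(0, -width / 2, 0),
                    clock9 = center + c(0, width / 2, 0),
                    articular_cortex_level = 0,
                    medial_cortex_level = vault)
}

test_that("scapular axis is the normalized centre-to-spine direction", {
  ax <- derive_scapular_axis(lm_fixture())
  expect_equal(ax$axis, c(1, 0, 0))
  expect_equal(ax$point, c(0, 0, 0))
  ax2 <- derive_scapular_axis(lm_fixture(spine = c(30, 40, 0)))
  expect_equal(ax2$axis, c(0.6, 0.8, 0))
  expect_error(glenoid_landmarks(c(0, 0, 0), c(0, 0, 0), c(0, 0, -1),
                                 c(0, -1, 0), c(0, 1, 0), 0, 30),
               "differ")
})

test_that("cylinder diameter is half the 3-9 o'clock distance", {
  expect_equal(cylinder_diameter(lm_fixture(width = 28)), 14)
  expect_equal(cylinder_diameter(lm_fixture(width = 30)), 15)
  set.seed(4)
  for (i in 1:10) {
    w <- runif(1L, 15, 40)
    expect_equal(cylinder_diameter(lm_fixture(width = w)), w / 2)
  }
})

test_that("vault cylinder spans articular to medial cortex", {
  v <- construct_vault_cylinder(lm_fixture(vault = 30))
  expect_equal(v$depth_mm, 30)
  expect_equal(v$start_offset_mm, 0)
  expect_equal(v$diameter_mm, 14)
  expect_error(construct_vault_cylinder(lm_fixture(), axis = c(-1, 0, 0)),
               "medial")
})

test_that("subchondral cylinder takes one third of the vault depth", {
  v <- construct_vault_cylinder(lm_fixture(vault = 30))
  s <- construct_subchondral_cylinder(v, necrosis_offset_mm = 0)
  expect_equal(s$depth_mm, 10)
  v24 <- construct_vault_cylinder(lm_fixture(vault = 24))
  s24 <- construct_subchondral_cylinder(v24, necrosis_offset_mm = 2)
  expect_equal(s24$depth_mm, 8)
  expect_equal(s24$start_offset_mm, 2)
  expect_equal(s24$axis, v24$axis)
  expect_equal(s24$diameter_mm, v24$diameter_mm)
  set.seed(6)
  for (i in 1:10) {
    d <- runif(1L, 10, 40)
    vv <- construct_vault_cylinder(lm_fixture(vault = d))
    expect_equal(construct_subchondral_cylinder(vv, 0)$depth_mm, d / 3)
  }
  expect_error(construct_subchondral_cylinder(v24, necrosis_offset_mm = 20),
               "medial cortex")
})

test_that("phantom landmarks reproduce the generator's configured geometry", {
  ph <- generate_phantom_ct(small_phantom_spec(seed = 3))
  lm <- ph$truth$landmarks
  expect_equal(derive_scapular_axis(lm)$axis, ph$truth$axis)
  expect_equal(cylinder_diameter(lm), ph$truth$width_mm / 2)
  expect_equal(construct_vault_cylinder(lm)$depth_mm,
               ph$truth$vault_depth_mm)
})

test_that("rasterized cylinder volume approaches the analytic volume", {
  vol_analytic <- pi * 5^2 * 10
  rel_err <- function(sp) {
    n <- as.integer(ceiling(24 / sp))
    g <- ct_volume(array(0, c(n, n, n)), spacing_mm = sp)
    c_mid <- (n - 1) * sp / 2
    voi <- cylinder_voi(c(2, c_mid, c_mid), c(1, 0, 0),
                        diameter_mm = 10, depth_mm = 10)
    abs(sum(rasterize_voi(voi, g)) * sp^3 - vol_analytic) / vol_analytic
  }
  expect_lt(rel_err(0.5), 0.02)
  # surface-layer error shrinks with the voxel size
  expect_lt(rel_err(0.3), rel_err(0.6))
  expect_lt(rel_err(0.3), 0.015)
})

test_that("rasterization is equivariant under origin shifts", {
  g1 <- ct_volume(array(0, c(24L, 24L, 24L)), spacing_mm = 0.5,
                  origin = c(0, 0, 0))
  g2 <- ct_volume(array(0, c(24L, 24L, 24L)), spacing_mm = 0.5,
                  origin = c(10, -4, 2.5))
  voi1 <- cylinder_voi(c(2, 5.75, 5.75), c(1, 0, 0), 6, 6)
  voi2 <- cylinder_voi(c(2, 5.75, 5.75) + c(10, -4, 2.5), c(1, 0, 0), 6, 6)
  expect_identical(rasterize_voi(voi1, g1), rasterize_voi(voi2, g2))
})

test_that("a cylinder outside the grid is rejected", {
  g <- ct_volume(array(0, c(16L, 16L, 16L)), spacing_mm = 0.5)
  voi <- cylinder_voi(c(100, 100, 100), c(1, 0, 0), 5, 5)
  expect_error(rasterize_voi(voi, g), "intersect")
})

test_that("the necrosis offset excludes a subchondral necrotic pocket", {
  cy <- (40 - 1) * 0.6 / 2
  pocket <- list(center_mm = c(2.4 + 1.8, cy, cy), radius_mm = 0.55,
                 bmd = 0)
  clean <- generate_phantom_ct(small_phantom_spec(noise_sd = 0, seed = 17))
  sick <- generate_phantom_ct(small_phantom_spec(noise_sd = 0, seed = 17,
                                                 necrotic_pocket = pocket))
  expect_false(identical(clean$truth$bmd$values, sick$truth$bmd$values))
  vault <- construct_vault_cylinder(sick$truth$landmarks)
  subch <- construct_subchondral_cylinder(vault, necrosis_offset_mm = 2)
  m_clean <- compute_voi_metrics(clean$truth$bmd, subch, 100)
  m_sick <- compute_voi_metrics(sick$truth$bmd, subch, 100)
  expect_equal(m_sick$bmd_mean, m_clean$bmd_mean)
  expect_equal(m_sick$bvtv, m_clean$bvtv)
})
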