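test_that("canonical markers sit at the defining positions", {
  g <- valve_geometry()
  mk0 <- canonical_markers(0)
  expect_equal(unlist(mk0[1, c("x", "y", "z")], use.names = FALSE),
               c(g$magnet_offset, 0, 0))
  expect_equal(unlist(mk0[2, c("x", "y", "z")], use.names = FALSE),
               c(-g$magnet_offset, 0, 0))
  expect_equal(unlist(mk0[4, c("x", "y", "z")], use.names = FALSE),
               c(g$rhs_offset, 0, 0))
  expect_equal(indicator_angle(mk0)$angle_deg, 0)
  # zone-center angles survive the full geometric chain exactly
  for (s in c(1, 4, 8)) {
    mk <- canonical_markers(setting_to_expected_angle(s))
    expect_identical(angle_to_setting(indicator_angle(mk)$angle_deg)$setting,
                     as.integer(s))
  }
})

test_that("phantom generation is deterministic and in-bounds", {
  sp <- phantom_spec(setting = 4, seed = 123)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_identical(a$truth$truth_setting, 4L)

  far <- phantom_spec(setting = 4, pose = make_pose(translation = c(500, 0, 0)))
  expect_error(make_phantom(far), "out of bounds")
})

test_that("label-map voxel counts track the analytic shape volumes", {
  g <- valve_geometry()
  vol_voxel <- prod(phantom_spec()$spacing)
  analytic <- c(4 / 3 * pi * g$magnet_radius^3,
                4 / 3 * pi * g$magnet_radius^3,
                2 * pi^2 * g$ring_radius * g$ring_tube_radius^2,
                4 / 3 * pi * g$rhs_radius^3,
                pi * g$tip_radius^2 * g$tip_length +
                  4 / 3 * pi * g$tip_radius^3) / vol_voxel
  withr::with_seed(31, poses <- replicate(3, random_pose(), simplify = FALSE))
  for (p in poses) {
    ph <- make_phantom(phantom_spec(setting = 5, pose = p, seed = 8))
    counts <- marker_centroids(ph$labels)$voxel_count
    expect_true(all(counts > 0))
    expect_true(all(abs(counts - analytic) / analytic < 0.2))
  }
})

test_that("cohorts are seed-reproducible with weighted, in-zone truths", {
  co <- make_cohort(20, seed = 5)
  co2 <- make_cohort(20, seed = 5)
  expect_identical(co$manifest, co2$manifest)
  zb <- zone_bounds(co$manifest$truth_setting)
  expect_true(all(co$manifest$truth_angle_deg >= zb$zone_lo &
                  co$manifest$truth_angle_deg < zb$zone_hi))

  one_hot <- make_cohort(12, setting_weights = c(0, 0, 0, 0, 1, 0, 0, 0),
                         seed = 2)
  expect_true(all(one_hot$manifest$truth_setting == 5L))
  expect_error(make_cohort(0), "positive")
  expect_error(make_cohort(5, setting_weights = rep(0, 8)), "weights")
})

test_that("empirical setting histogram is consistent with the weights", {
  w <- default_setting_weights()
  co <- make_cohort(75, seed = 7)
  obs <- tabulate(co$manifest$truth_setting, nbins = 8)
  chi <- suppressWarnings(stats::chisq.test(obs, p = w / sum(w)))
  expect_gt(chi$p.value, 0.001)
})

test_that("a cohort round-trips through disk with an aligned manifest", {
  dir <- withr::local_tempdir()
  co <- make_cohort(3, seed = 9, volume_shape = c(80, 80, 80))
  man <- write_cohort(co, dir)
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(man$volume_path), file.exists(man$labels_path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  lm <- read_labelmap(man$labels_path[2])
  ph <- make_phantom(co$specs[[2]])
  expect_identical(lm$labels, ph$labels$labels)
  res <- predict_setting(lm)
  expect_identical(res$setting, co$manifest$truth_setting[2])
})
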