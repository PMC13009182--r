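test_that("marker centroids are unweighted means in physical mm", {
  lm <- lm_from_points(list(`4` = c(5, 5, 5)))
  mk <- marker_centroids(lm)
  expect_equal(unlist(mk[mk$label == 4, c("x", "y", "z")], use.names = FALSE),
               c(5, 5, 5))
  expect_equal(mk$voxel_count, c(0L, 0L, 0L, 1L, 0L))

  lm2 <- lm_from_points(list(`1` = rbind(c(0, 0, 0), c(2, 0, 0))))
  mk2 <- marker_centroids(lm2)
  expect_equal(unlist(mk2[1, c("x", "y", "z")], use.names = FALSE), c(1, 0, 0))

  empty <- marker_centroids(label_map(array(0L, c(4, 4, 4))))
  expect_true(all(empty$voxel_count == 0L))
  expect_true(all(is.na(empty$x)))
})

test_that("marker centroids match the brute-force per-voxel oracle", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      dims <- sample(5:12, 3, replace = TRUE)
      arr <- array(sample(0:5, prod(dims), replace = TRUE,
                          prob = c(.7, rep(.06, 5))), dims)
      aff <- random_affine()
    })
    lm <- label_map(arr, aff)
    got <- marker_centroids(lm)
    want <- oracle_centroids(lm)
    for (l in 1:5)
      expect_equal(unlist(got[l, c("x", "y", "z")], use.names = FALSE),
                   want[[l]], tolerance = 1e-12)
  }
})

test_that("valve frame axes follow the RC/RHS/TIP construction", {
  mk <- markers_from_points(list(rotating_construct = c(0, 0, 0),
                                 rhs_marker = c(10, 0, 0),
                                 distal_tip = c(0, 30, 0)))
  fr <- valve_frame(mk)
  expect_equal(fr$ref_axis, c(1, 0, 0))
  expect_equal(fr$normal, c(0, 0, 1))
  expect_equal(fr$flow_axis, c(0, 1, 0))
  expect_lt(abs(sum(fr$ref_axis * fr$normal)), 1e-9)
})

test_that("missing or collinear plane markers raise typed errors", {
  mk <- markers_from_points(list(rotating_construct = c(0, 0, 0),
                                 distal_tip = c(0, 30, 0)))
  err <- expect_error(valve_frame(mk), "rhs_marker",
                      class = "certasdial_missing_marker")
  expect_identical(err$missing_markers, "rhs_marker")

  col <- markers_from_points(list(rotating_construct = c(0, 0, 0),
                                  rhs_marker = c(1, 0, 0),
                                  distal_tip = c(2, 0, 0)))
  expect_error(valve_frame(col), "degenerate valve plane",
               class = "certasdial_degenerate")
})

test_that("indicator angle convention: 0 on the RHS axis, 180 opposite", {
  base <- list(rotating_construct = c(0, 0, 0), rhs_marker = c(10, 0, 0),
               distal_tip = c(0, 30, 0))
  mk0 <- markers_from_points(c(base, list(magnet_with_ball = c(3.5, 0, 0),
                                          magnet_without_ball = c(-3.5, 0, 0))))
  expect_equal(indicator_angle(mk0)$angle_deg, 0)

  mk180 <- markers_from_points(c(base, list(magnet_with_ball = c(-3.5, 0, 0),
                                            magnet_without_ball = c(3.5, 0, 0))))
  expect_equal(indicator_angle(mk180)$angle_deg, 180)

  # swapping magnet labels rotates the measurement by 180
  for (th in c(-50, 12, 101, 260)) {
    mk <- canonical_markers(th)
    sw <- mk
    sw$label <- c(2L, 1L, 3:5)
    sw$name[1:2] <- sw$name[2:1]
    expect_equal(indicator_angle(sw)$angle_deg,
                 normalize_angle(indicator_angle(mk)$angle_deg + 180),
                 tolerance = 1e-9)
  }

  noball <- markers_from_points(c(base, list(magnet_without_ball = c(-3.5, 0, 0))))
  expect_error(indicator_angle(noball), "magnet_with_ball",
               class = "certasdial_missing_marker")

  perp <- markers_from_points(c(base, list(magnet_with_ball = c(0, 0, 3.5),
                                           magnet_without_ball = c(0, 0, -3.5))))
  expect_error(indicator_angle(perp), "degenerate indicator",
               class = "certasdial_degenerate")
})

test_that("angle measurement is invariant under rigid motions", {
  withr::with_seed(11, {
    for (rep in 1:100) {
      th <- runif(1, -90, 270)
      mk <- canonical_markers(th)
      pose <- random_pose()
      pose$translation <- runif(3, -50, 50)
      got <- indicator_angle(transform_markers(mk, pose))$angle_deg
      d <- abs(got - normalize_angle(th))
      expect_lt(min(d, 360 - d), 1e-6)
    }
  })
})

test_that("reflection through the valve plane leaves the angle unchanged", {
  withr::with_seed(13, {
    for (rep in 1:25) {
      th <- runif(1, -90, 270)
      mk <- transform_markers(canonical_markers(th), random_pose())
      fr <- valve_frame(mk)
      p <- as.matrix(mk[, c("x", "y", "z")])
      h <- (p - matrix(fr$origin, 5, 3, byrow = TRUE)) %*% fr$normal
      refl <- p - 2 * h %*% t(fr$normal)
      mk$x <- refl[, 1]; mk$y <- refl[, 2]; mk$z <- refl[, 3]
      d <- abs(indicator_angle(mk)$angle_deg - normalize_angle(th))
      expect_lt(min(d, 360 - d), 1e-6)
    }
  })
})

test_that("phantom round trip recovers a mid-zone truth angle", {
  withr::with_seed(77, pose <- random_pose())
  ph <- make_phantom(phantom_spec(angle_deg = 112.5, pose = pose, seed = 99))
  res <- indicator_angle(marker_centroids(ph$labels))
  expect_lt(abs(res$angle_deg - 112.5), 2)
})
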