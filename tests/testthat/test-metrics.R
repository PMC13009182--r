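mask_pair <- function(seed, dims = c(6, 6, 6)) {
  withr::with_seed(seed, {
    a <- array(sample(0:5, prod(dims), TRUE, prob = c(.6, rep(.08, 5))), dims)
    b <- array(sample(0:5, prod(dims), TRUE, prob = c(.6, rep(.08, 5))), dims)
  })
  list(label_map(a), label_map(b))
}

test_that("dice and iou follow their definitions and conventions", {
  same <- lm_from_points(list(`1` = rbind(c(0, 0, 0), c(1, 0, 0))))
  expect_equal(dice(same, same, 1), 1)
  expect_equal(iou(same, same, 1), 1)

  other <- lm_from_points(list(`1` = rbind(c(5, 5, 5), c(6, 5, 5))))
  expect_equal(dice(same, other, 1), 0)
  expect_equal(iou(same, other, 1), 0)

  half <- lm_from_points(list(`1` = rbind(c(1, 0, 0), c(2, 0, 0))))
  expect_equal(dice(same, half, 1), 0.5)
  expect_equal(iou(same, half, 1), 1 / 3)

  # label absent from both maps: perfect agreement by convention
  expect_equal(dice(same, half, 5), 1)
  expect_equal(iou(same, half, 5), 1)
  # absent from exactly one
  expect_equal(dice(same, lm_from_points(list()), 1), 0)

  expect_error(dice(same, label_map(array(0L, c(3, 3, 3))), 1), "geometry")
})

test_that("IoU = DSC / (2 - DSC) identity holds on random mask pairs", {
  for (seed in 1:40) {
    p <- mask_pair(seed)
    for (l in 1:5) {
      d <- dice(p[[1]], p[[2]], l)
      expect_equal(iou(p[[1]], p[[2]], l), d / (2 - d), tolerance = 1e-12)
    }
  }
  ov <- overlap_scores(mask_pair(99)[[1]], mask_pair(98)[[2]])
  expect_true(all(ov$iou <= ov$dsc + 1e-12))
})

test_that("Clopper-Pearson intervals match exact beta quantiles", {
  ci <- clopper_pearson(72, 75)
  expect_equal(round(c(ci$lower, ci$upper), 3), c(0.888, 0.992))
  ci2 <- clopper_pearson(61, 75)
  expect_equal(round(c(ci2$lower, ci2$upper), 3), c(0.707, 0.894))
  expect_equal(clopper_pearson(0, 10)$lower, 0)
  expect_equal(clopper_pearson(10, 10)$upper, 1)
  ci3 <- clopper_pearson(5, 20)
  expect_true(ci3$lower < ci3$estimate & ci3$estimate < ci3$upper)
  expect_error(clopper_pearson(5, 4), "k <= n")
  expect_error(clopper_pearson(2, 10, level = 1.2), "level")
})

test_that("report-style proportion formatting drops trailing .0", {
  expect_identical(format_proportion(72, 75), "96%")
  expect_identical(format_proportion(73, 75), "97.3%")
  expect_identical(format_proportion(391, 486), "80.5%")
  expect_equal(proportion_percent(61, 75), 81.3)
})

test_that("confusion matrix keeps undeterminable cases out but counted", {
  truth <- c(4, 4, 5, 2, 8)
  pred <- c(4, 3, NA, 2, 8)
  cm <- confusion_matrix(truth, pred)
  expect_equal(sum(cm$matrix), 4)
  expect_equal(cm$n_undeterminable, 1)
  expect_equal(unname(rowSums(cm$matrix)[4]), 2)
  expect_equal(cm$matrix[4, 3], 1L)
  expect_error(confusion_matrix(c(1, 2), c(1)), "equal length")
})

test_that("accuracies use all cases as denominator with exact CIs", {
  # 61 exact among 75, 11 adjacent misses, 1 far miss, 2 undeterminable
  truth <- rep(4L, 75)
  pred <- c(rep(4L, 61), rep(5L, 11), 7L, NA, NA)
  rep_ <- evaluate_predictions(tibble::tibble(truth_setting = truth,
                                              setting = pred))
  acc <- tidy(rep_)
  exact <- acc[acc$metric == "exact", ]
  expect_equal(exact$percent, 81.3)
  expect_equal(round(c(exact$lower, exact$upper), 3), c(0.707, 0.894))
  adj <- acc[acc$metric == "adjacent", ]
  expect_equal(adj$k, 72L)
  expect_equal(adj$percent, 96)
  expect_gte(adj$estimate, exact$estimate)
  det <- acc[acc$metric == "determinable", ]
  expect_equal(det$percent, 97.3)

  perfect <- evaluate_predictions(tibble::tibble(truth_setting = 1:8,
                                                 setting = 1:8))
  pt <- tidy(perfect)
  expect_true(all(pt$estimate == 1))
  expect_true(all(pt$upper == 1))
  g <- glance(perfect)
  expect_equal(g$n_total, 8L)
  expect_equal(g$estimate_exact, 1)
})

test_that("adjacent accuracy dominates exact accuracy on random data", {
  withr::with_seed(61, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      truth <- sample(1:8, n, TRUE)
      pred <- sample(1:8, n, TRUE)
      pred[sample(n, max(0, n %/% 10))] <- NA
      r <- evaluate_predictions(tibble::tibble(truth_setting = truth,
                                               setting = pred))
      acc <- tidy(r)
      expect_gte(acc$estimate[acc$metric == "adjacent"],
                 acc$estimate[acc$metric == "exact"])
      expect_equal(sum(r$confusion$matrix) + r$confusion$n_undeterminable, n)
    }
  })
})

test_that("angle summaries report n-1 SDs and flag off-zone means", {
  rec <- tibble::tibble(truth_setting = c(3, 3, 3, 5),
                        angle_deg = c(22.5, 22.5, 22.5, 100))
  s <- angle_summary(rec)
  expect_equal(s$mean_angle[s$setting == 3], 22.5)
  expect_equal(s$sd_angle[s$setting == 3], 0)
  expect_equal(s$expected_angle, c(22.5, 112.5))
  expect_true(is.na(s$sd_angle[s$setting == 5]))   # single sample: no SD
  expect_false(s$expected_outside_2sd[s$setting == 5])

  off <- tibble::tibble(truth_setting = rep(2L, 4),
                        angle_deg = c(50, 51, 52, 53))
  s2 <- angle_summary(off)
  expect_true(s2$expected_outside_2sd)   # expected -22.5 far outside
})

test_that("simulated cohort angle means stay inside their zones", {
  co <- make_cohort(60, seed = 19)
  rec <- tibble::tibble(truth_setting = co$manifest$truth_setting,
                        angle_deg = co$manifest$truth_angle_deg)
  s <- angle_summary(rec)
  zb <- zone_bounds(s$setting)
  expect_true(all(s$mean_angle >= zb$zone_lo & s$mean_angle < zb$zone_hi))
})

test_that("evaluation reports serialize to JSON and CSV", {
  r <- evaluate_predictions(tibble::tibble(truth_setting = c(1, 2, 3),
                                           setting = c(1L, 2L, 4L),
                                           angle_deg = c(-70, -20, 70)))
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(r, jf, cf)
  back <- jsonlite::read_json(jf)
  expect_equal(back$n_total, 3)
  expect_equal(length(back$accuracy), 3)
  cm <- utils::read.csv(cf, row.names = 1)
  expect_equal(dim(cm), c(8, 8))
})
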