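test_that("the packaged radiological table carries the expected structure", {
  tb <- radiology_reference()
  expect_equal(nrow(tb), 15)
  expect_setequal(unique(tb$movement), c("FLX", "EXT", "LB"))
  # cumulative means decrease from L1 to L5 within every movement
  for (mv in unique(tb$movement)) {
    sub <- tb[tb$movement == mv, ]
    expect_true(all(diff(sub$mean_deg) < 0))
  }
})

test_that("zero-SD cohorts reproduce the reference means exactly", {
  stats0 <- radiology_reference()
  stats0$sd_deg <- 0
  spec <- cohort_spec(n_subjects = 5, angle_stats = stats0, seed = 3)
  coh <- generate_cohort(spec)
  ref <- stats0[, c("vertebra", "movement", "mean_deg")]
  j <- merge(coh, ref, by = c("vertebra", "movement"))
  expect_equal(j$angle_deg, j$mean_deg, tolerance = 1e-12)
})

test_that("a default 25-subject cohort recovers the flexion mean within sampling error", {
  coh <- generate_cohort(cohort_spec(seed = 11))
  stats <- cohort_stats(coh, "FLX")
  m <- stats$mean_deg[stats$vertebra == "L1"]
  expect_lt(abs(m - 33.94), 3 * 4.91 / sqrt(25))
  expect_true(all(stats$sd_deg >= 0))
  # ages and weights inside the stated ranges
  expect_true(all(coh$age >= 23 & coh$age <= 33))
  expect_true(all(coh$weight >= 72.1 & coh$weight <= 81.7))
  # monotone cumulative angles within each subject and movement
  chk <- coh |>
    dplyr::group_by(.data$subject_id, .data$movement) |>
    dplyr::summarise(mono = all(diff(.data$angle_deg) <= 1e-9),
                     .groups = "drop")
  expect_true(all(chk$mono))
})

test_that("large cohorts recover the reference means and SDs (n = 10000)", {
  coh <- generate_cohort(cohort_spec(n_subjects = 10000, seed = 5))
  ref <- radiology_reference()
  for (mv in c("FLX", "LB")) {
    stats <- cohort_stats(coh, mv)
    sub <- merge(stats, ref[ref$movement == mv, ], by = "vertebra")
    # means within ~4 standard errors (isotonic correction bias is tiny for
    # the monotone reference means)
    expect_lt(max(abs(sub$mean_deg.x - sub$mean_deg.y) /
                    (sub$sd_deg.y / sqrt(10000) + 0.02)), 5)
  }
  stats_lb <- cohort_stats(coh, "LB")
  sd_l1 <- stats_lb$sd_deg[stats_lb$vertebra == "L1"]
  expect_lt(abs(sd_l1 - 2.39) / 2.39, 0.05)
})

test_that("cohorts are bit-reproducible under a fixed seed", {
  s <- cohort_spec(seed = 21)
  expect_identical(generate_cohort(s), generate_cohort(s))
})

test_that("cohort statistics use the (n-1)-denominator definition", {
  rec <- tibble::tibble(subject_id = c(1, 2), age = 25, weight = 75,
                        movement = "FLX", vertebra = "L1",
                        angle_deg = c(10, 20))
  st <- cohort_stats(rec, "FLX")
  expect_equal(st$mean_deg, 15)
  expect_equal(st$sd_deg, 7.0711, tolerance = 1e-4)
  expect_error(cohort_stats(rec[1, ], "FLX"), "two subjects")
  expect_error(cohort_stats(rec, "AR"), "no records")
})

test_that("agreement reports flag the one- and two-SD bands", {
  cohort <- radiology_reference()
  cohort <- cohort[cohort$movement == "FLX", ]
  model <- cohort
  model$cumulative_deg <- model$mean_deg
  rep0 <- agreement_report(model, cohort)
  expect_true(all(rep0$within_1sd))
  expect_equal(max(abs(rep0$deviation_deg)), 0)

  model$cumulative_deg <- model$mean_deg + 2.1 * model$sd_deg
  rep2 <- agreement_report(model, cohort)
  expect_true(all(!rep2$within_1sd))
  expect_true(all(!rep2$within_2sd))

  # the printed flexion maximum sits 0.46 degrees above the radiology mean
  m1 <- model[model$vertebra == "L1", ]
  m1$cumulative_deg <- 34.40
  r1 <- agreement_report(m1, cohort[cohort$vertebra == "L1", ])
  expect_true(r1$within_1sd)
  expect_equal(r1$deviation_deg, 0.46, tolerance = 1e-9)
})

test_that("noise-free landmarks reproduce the generated angles through the measurement path", {
  spec <- cohort_spec(n_subjects = 3, seed = 9)
  coh <- generate_cohort(spec)
  lm <- cohort_landmarks(coh, geom_full, noise_sd = 0, seed = 1)
  ang <- angles_from_landmarks(lm)
  j <- merge(ang, coh, by = c("subject_id", "movement", "vertebra"))
  expect_equal(j$angle_deg.x, j$angle_deg.y, tolerance = 1e-6)
  # noisy landmarks stay close but not identical
  lmn <- cohort_landmarks(coh, geom_full, noise_sd = 0.3, seed = 2)
  angn <- angles_from_landmarks(lmn)
  jn <- merge(angn, coh, by = c("subject_id", "movement", "vertebra"))
  expect_gt(max(abs(jn$angle_deg.x - jn$angle_deg.y)), 1e-4)
  expect_lt(max(abs(jn$angle_deg.x - jn$angle_deg.y)), 5)
})
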