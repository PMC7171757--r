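# Cohort generator: validation, determinism, baseline survival calibration.

test_that("invalid cohort specifications are rejected with named fields", {
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(censoring_rate = 1), "censoring_rate")
  expect_error(cohort_spec(volume_shape = c(20L, 20L, 8L),
                           voxel_spacing_mm = c(1, 1, 1)),
               "roi_radius_range_mm")
  expect_error(cohort_spec(roi_radius_range_mm = list(tumor = c(5, 2),
                                                      node = c(4, 7))),
               "roi_radius_range_mm")
  expect_error(cohort_spec(effect_sizes = list(LC = c(bogus_latent = 1),
                                               RC = numeric(), DMFS = numeric(),
                                               OS = numeric())),
               "effect_sizes")
})

test_that("identical seeds reproduce the cohort bit-identically", {
  spec <- small_cohort_spec(3, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(lapply(a, `[[`, "latent_params"),
                   lapply(b, `[[`, "latent_params"))
  expect_identical(a[[2]]$volumes$T2$intensities, b[[2]]$volumes$T2$intensities)
  expect_identical(cohort_outcomes(a), cohort_outcomes(b))
  c2 <- generate_cohort(small_cohort_spec(3, seed = 8))
  expect_false(identical(cohort_outcomes(a), cohort_outcomes(c2)))
})

test_that("patient invariants hold: nonempty in-bounds masks, positive times", {
  coh <- generate_cohort(small_cohort_spec(5, seed = 21))
  for (p in coh) {
    expect_gt(sum(p$masks$tumor$voxels), 0)
    expect_gt(sum(p$masks$node$voxels), 0)
    expect_false(any(p$masks$tumor$voxels & p$masks$node$voxels))
    expect_true(all(p$outcomes$time_months > 0))
    expect_true(all(p$outcomes$event %in% 0:1))
    expect_setequal(p$outcomes$endpoint, c("LC", "RC", "DMFS", "OS"))
  }
})

test_that("null-effect, uncensored survival matches the exponential baseline", {
  # bypass image synthesis: the tabular path shares the survival machinery
  fc <- generate_feature_cohort(n_patients = 2000, n_features = 2,
                                effect_sizes = numeric(), censoring_rate = 0,
                                seed = 99, baseline_hazard_scale = 36)
  expect_true(all(fc$outcomes$event == 1))
  ks <- suppressWarnings(
    stats::ks.test(fc$outcomes$time_months, pexp, rate = 1 / 36))
  expect_gt(ks$p.value, 0.01)
})

test_that("censoring calibration approaches the requested rate", {
  fc <- generate_feature_cohort(n_patients = 4000, n_features = 2,
                                effect_sizes = numeric(),
                                censoring_rate = 0.3, seed = 5)
  expect_equal(mean(fc$outcomes$event == 0), 0.3, tolerance = 0.05)
})

test_that("feature cohort is deterministic and validates inputs", {
  a <- generate_feature_cohort(50, 10, c(0.5), seed = 3)
  b <- generate_feature_cohort(50, 10, c(0.5), seed = 3)
  expect_identical(a, b)
  expect_error(generate_feature_cohort(1, 5, seed = 1), "n_patients")
  expect_error(generate_feature_cohort(10, 1, c(1, 1), seed = 1), "n_features")
})

test_that("the random split partitions the cohort at the requested sizes", {
  ids <- data.frame(patient_id = sprintf("P%03d", 1:93))
  sp <- split_cohort(ids, 2 / 3, seed = 4)
  expect_equal(nrow(sp$train), 62)
  expect_equal(nrow(sp$validation), 31)
  expect_setequal(c(sp$train$patient_id, sp$validation$patient_id),
                  ids$patient_id)
  expect_length(intersect(sp$train_idx, sp$validation_idx), 0)

  tiny <- split_cohort(list("a", "b"), 0.5, seed = 1)
  expect_length(tiny$train, 1)
  expect_length(tiny$validation, 1)

  sp2 <- split_cohort(ids, 2 / 3, seed = 4)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_cohort(ids, 2 / 3, seed = 5)
  expect_false(identical(sp$train_idx, sp3$train_idx))

  expect_error(split_cohort(ids, 1.2, seed = 1), "train_fraction")
  expect_error(split_cohort(list("a", "b"), 0.1, seed = 1), "empty")
})
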