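test_that("the registration count formula holds for any design", {
  # 1 patient, 2 series, RV0 only, no full volume -> exactly 1 registration
  cfg <- study_config(n_patients = 1,
                      phantom = quick_phantom(n_series = 2, seed = 71),
                      margins_mm = numeric(0), include_full_volume = FALSE)
  rep1 <- run_study(cfg)
  expect_equal(rep1$n_registrations, 1L)
  # 1 patient, 3 series, margins {10}, with full -> 2 * 3 = 6
  cfg2 <- study_config(n_patients = 1,
                       phantom = quick_phantom(n_series = 3, seed = 72),
                       margins_mm = 10)
  rep2 <- run_study(cfg2)
  expect_equal(rep2$n_registrations,
               1L * (3L - 1L) * (length(cfg2$margins_mm) + 1L + 1L))
})

test_that("a zero-motion, zero-noise study registers everything to within half a voxel", {
  ph <- quick_phantom(n_series = 2, seed = 73,
                      prostate_motion_sd_mm = c(0, 0, 0),
                      prostate_rotation_sd_deg = 0,
                      organ_variation_scale = 0, noise_sigma = 0)
  cfg <- study_config(n_patients = 2, phantom = ph, margins_mm = 10,
                      seed = 73)
  rep <- run_study(cfg)
  half_voxel <- max(ph$spacing_mm) / 2
  expect_true(all(rep$distances$norm_mm < half_voxel))
})

test_that("rerunning the same configuration reproduces the report exactly", {
  cfg <- study_config(n_patients = 1,
                      phantom = quick_phantom(n_series = 2, seed = 74),
                      margins_mm = 10, seed = 74)
  r1 <- run_study(cfg)
  r2 <- run_study(cfg)
  expect_identical(r1$distances$norm_mm, r2$distances$norm_mm)
  expect_identical(r1$distances$final_metric, r2$distances$final_metric)
})

test_that("study reports expose tidy, glance and autoplot interfaces", {
  cfg <- study_config(n_patients = 2,
                      phantom = quick_phantom(n_series = 2, seed = 75),
                      margins_mm = 10, seed = 75)
  rep <- run_study(cfg)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), rep$n_registrations)
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_registrations, rep$n_registrations)
  expect_false(is.na(gl$sd_ap_rv0_mm))
  expect_s3_class(autoplot(rep), "ggplot")
  expect_output(print(rep), "registrations")
  # F-tests cover every axis for every subvolume
  expect_equal(sort(unique(rep$f_tests$axis)), sort(c("RL", "AP", "CC", "norm")))
})

test_that("a study directory persists and round-trips through the loaders", {
  dir <- withr::local_tempdir()
  p <- generate_patient(quick_phantom(n_series = 2, seed = 76))
  write_patient_series(p, dir)
  p2 <- load_external_series(dir)
  expect_length(p2$volumes, 2)
  expect_equal(p2$volumes[[1]]$data, p$volumes[[1]]$data, tolerance = 1e-4)
  expect_identical(p2$prostate_masks[[1]]$data, p$prostate_masks[[1]]$data)
  expect_equal(p2$true_prostate_transforms[[2]]$translation_mm,
               p$true_prostate_transforms[[2]]$translation_mm,
               tolerance = 1e-12)
  # a loaded series can drive the study machinery directly
  cfg <- study_config(margins_mm = 10, include_full_volume = FALSE)
  rep <- run_study(cfg, patients = list(p2))
  expect_equal(rep$n_registrations, 2L)
})

test_that("external loading validates its preconditions", {
  dir <- withr::local_tempdir()
  p <- generate_patient(quick_phantom(n_series = 2, seed = 77))
  write_volume(p$volumes[[1]], file.path(dir, "volume_00.nii.gz"))
  expect_error(load_external_series(dir), "at least two series")
  # mismatched geometry under strict mode
  small <- generate_patient(phantom_config(grid_shape = c(48, 48, 30),
                                           n_series = 2, seed = 77))
  write_volume(small$volumes[[2]], file.path(dir, "volume_01.nii.gz"))
  write_mask(p$prostate_masks[[1]], file.path(dir, "prostate_mask_00.nii.gz"))
  expect_error(load_external_series(dir, strict = TRUE), "geometry")
  # non-strict mode resamples onto the reference grid
  p3 <- load_external_series(dir)
  expect_equal(dim(p3$volumes[[2]]$data), dim(p3$volumes[[1]]$data))
})

test_that("study configuration validates margins", {
  expect_error(study_config(margins_mm = c(10, 10)), "strictly increasing")
  expect_error(study_config(margins_mm = c(-5, 10)), "strictly increasing")
})
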