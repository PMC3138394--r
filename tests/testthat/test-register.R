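test_that("self-registration recovers the identity", {
  p <- generate_patient(quick_phantom(n_series = 2, seed = 31))
  v <- p$volumes[[1]]
  res <- register_rigid(v, v, p$prostate_masks[[1]])
  expect_true(res$converged)
  expect_false(res$flagged)
  expect_lt(max(abs(res$transform$translation_mm)), 0.1)
  expect_lt(rotation_angle_deg(res$transform), 0.1)
})

test_that("a known translation is recovered within 0.5 mm per axis", {
  # resample-based fixtures carry an interpolation floor that scales with
  # voxel size; ~3 mm voxels keep it well under the 0.5 mm budget
  p <- generate_patient(phantom_config(grid_shape = c(144, 144, 90),
                                       n_series = 2, seed = 32,
                                       organ_variation_scale = 0,
                                       noise_sigma = 0))
  mv <- p$volumes[[1]]
  shift <- c(4.0, -2.0, 1.7)
  tr_true <- rigid_transform(translation_mm = shift)
  fx <- resample_volume(mv, tr_true, fill = 5)
  fx <- apply_noise(fx, 2, seed = 99)  # mild noise
  res <- register_rigid(fx, mv, p$prostate_masks[[1]])
  expect_true(res$converged)
  ctr <- p$prostate_center_mm
  err <- transform_point(res$transform, ctr) - (ctr + shift)
  expect_lt(max(abs(err)), 0.5)
})

test_that("a known rotation plus shift is recovered within 0.5 deg / 0.5 mm", {
  # finer grid than the study default: at 4 mm voxels the interpolation
  # floor of the resampled fixture biases the rotation optimum by ~2 deg,
  # so the oracle itself needs ~2 mm voxels to be trustworthy at 0.5 deg
  p <- generate_patient(phantom_config(grid_shape = c(192, 192, 120),
                                       n_series = 2, seed = 33,
                                       organ_variation_scale = 0,
                                       noise_sigma = 0))
  mv <- p$volumes[[1]]
  ctr <- p$prostate_center_mm
  tr_true <- rigid_transform(versor_from_axis_angle(c(0, 0, 1), 3),
                             c(0, 3, 0), ctr)
  fx <- resample_volume(mv, tr_true, fill = 5)
  res <- register_rigid(fx, mv, p$prostate_masks[[1]])
  err_t <- transform_point(res$transform, ctr) - transform_point(tr_true, ctr)
  expect_lt(max(abs(err_t)), 0.5)
  rel <- transform_compose(res$transform, transform_invert(tr_true))
  expect_lt(rotation_angle_deg(rel), 0.5)
})

test_that("RV0 registration recovers phantom motion to subvoxel accuracy", {
  errs <- sapply(41:43, function(s) {
    p <- generate_patient(phantom_config(n_series = 2, seed = s))
    res <- register_rigid(p$volumes[[2]], p$volumes[[1]],
                          p$prostate_masks[[1]])
    ctr <- p$prostate_center_mm
    abs(transform_point(res$transform, ctr) -
          transform_point(p$true_prostate_transforms[[2]], ctr))
  })
  # half a voxel at the default study grid, per axis
  expect_true(all(errs < 0.5 * c(4.68, 4.2412, 3.4)))
})

test_that("forward and backward registrations are mutually inverse", {
  p <- generate_patient(phantom_config(n_series = 2, seed = 34,
                                       noise_sigma = 0))
  ab <- register_rigid(p$volumes[[2]], p$volumes[[1]], p$prostate_masks[[1]])
  ba <- register_rigid(p$volumes[[1]], p$volumes[[2]], p$prostate_masks[[2]])
  rel <- transform_compose(ab$transform, ba$transform)
  ctr <- p$prostate_center_mm
  expect_lt(max(abs(transform_point(rel, ctr) - ctr)), 1)
  expect_lt(rotation_angle_deg(rel), 1)
})

test_that("descent never ends above its starting metric and flags follow the contract", {
  p <- generate_patient(quick_phantom(n_series = 2, seed = 35))
  res <- register_rigid(p$volumes[[2]], p$volumes[[1]], p$prostate_masks[[1]])
  expect_true(length(res$metric_trace) >= 1)
  expect_lte(res$final_metric, res$metric_trace[1])
  expect_lte(res$iterations, optimizer_config()$max_iterations)
  # flagged implies non-convergence or metric above the configured threshold
  opt <- optimizer_config(flag_metric_threshold = 1e-6)
  res2 <- register_rigid(p$volumes[[2]], p$volumes[[1]],
                         p$prostate_masks[[1]], opt = opt)
  expect_true(res2$flagged)
  expect_true(!res2$converged || res2$final_metric > opt$flag_metric_threshold)
})

test_that("metric sampling stride keeps the solution consistent", {
  p <- generate_patient(quick_phantom(n_series = 2, seed = 36))
  rv1 <- expand_mask(p$prostate_masks[[1]], 10)
  r1 <- register_rigid(p$volumes[[2]], p$volumes[[1]], rv1)
  r2 <- register_rigid(p$volumes[[2]], p$volumes[[1]], rv1, stride = 2L)
  expect_lt(max(abs(r1$transform$translation_mm - r2$transform$translation_mm)),
            1.5)
})

test_that("optimizer configuration validates its invariants", {
  expect_error(optimizer_config(min_step_mm = 0))
  expect_error(optimizer_config(min_step_mm = 3, max_step_mm = 2))
  expect_error(optimizer_config(relaxation = 1))
  expect_error(optimizer_config(max_iterations = 0))
})
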