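make_distances <- function(deltas, volumes, pair_ids) {
  tibble::tibble(
    pair_id = pair_ids,
    registration_volume = volumes,
    delta_rl_mm = deltas[, 1], delta_ap_mm = deltas[, 2],
    delta_cc_mm = deltas[, 3],
    norm_mm = sqrt(rowSums(deltas^2))
  )
}

test_that("com_distance is zero for a perfect registration and exact for shifts", {
  p <- generate_patient(quick_phantom(n_series = 2, seed = 61))
  half_voxel <- max(p$volumes[[1]]$spacing_mm) / 2
  cd <- com_distance(p$true_prostate_transforms[[2]], p$prostate_masks[[1]],
                     p$prostate_masks[[2]])
  expect_lt(cd$norm_mm, half_voxel)
  # identity transform, target mask shifted by 4 voxels x 1.17 mm in AP
  m <- binary_mask(array(FALSE, c(20, 20, 20)), c(1.17, 1.17, 1.7))
  m$data[9:12, 5:8, 9:12] <- TRUE
  m2 <- binary_mask(array(FALSE, c(20, 20, 20)), c(1.17, 1.17, 1.7))
  m2$data[9:12, 9:12, 9:12] <- TRUE
  cd2 <- com_distance(rigid_transform(), m, m2)
  expect_equal(cd2$norm_mm, 4.68, tolerance = 1e-9)
  expect_equal(cd2$delta_ap_mm, 4.68, tolerance = 1e-9)
})

test_that("com_distance agrees with an independent COM computation", {
  p <- generate_patient(quick_phantom(n_series = 2, seed = 62))
  res <- register_rigid(p$volumes[[2]], p$volumes[[1]], p$prostate_masks[[1]])
  cd <- com_distance(res, p$prostate_masks[[1]], p$prostate_masks[[2]])
  want <- unname(colMeans(mask_points_oracle(p$prostate_masks[[2]]))) -
    transform_point(res$transform,
                    unname(colMeans(mask_points_oracle(p$prostate_masks[[1]]))))
  expect_equal(c(cd$delta_rl_mm, cd$delta_ap_mm, cd$delta_cc_mm),
               unname(want), tolerance = 1e-10)
  expect_equal(cd$norm_mm, sqrt(sum(want^2)), tolerance = 1e-10)
})

test_that("per-axis statistics match hand and two-pass computations", {
  # all deltas identical -> SD 0
  d0 <- make_distances(matrix(1.5, 4, 3), rep("RV0", 4), paste0("p", 1:4))
  s0 <- per_axis_statistics(d0)
  expect_true(all(s0$sd_mm == 0))
  # AP components +1 and -1 -> mean 0, SD sqrt(2)
  d1 <- make_distances(rbind(c(0, 1, 0), c(0, -1, 0)), rep("RV0", 2),
                       c("p1", "p2"))
  s1 <- per_axis_statistics(d1)
  ap <- s1[s1$axis == "AP", ]
  expect_equal(ap$mean_mm, 0)
  expect_equal(ap$sd_mm, sqrt(2))
  # 30 random vectors vs the textbook two-pass formula
  set.seed(63)
  dm <- matrix(rnorm(90, 0, 3), 30, 3)
  d2 <- make_distances(dm, rep("full", 30), paste0("p", 1:30))
  s2 <- per_axis_statistics(d2)
  two_pass <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  expect_equal(s2$sd_mm[s2$axis == "RL"], two_pass(dm[, 1]), tolerance = 1e-12)
  expect_equal(s2$mean_mm[s2$axis == "CC"], mean(dm[, 3]), tolerance = 1e-12)
  nrm <- sqrt(rowSums(dm^2))
  expect_equal(s2$sd_mm[s2$axis == "norm"], two_pass(nrm), tolerance = 1e-12)
  expect_error(per_axis_statistics(d1[1, ]), "insufficient pairs")
})

test_that("SD is shift-invariant; only norm statistics are rotation-invariant", {
  set.seed(64)
  dm <- matrix(rnorm(60, 1, 2), 20, 3)
  d <- make_distances(dm, rep("RV0", 20), paste0("p", 1:20))
  s <- per_axis_statistics(d)
  dsh <- make_distances(sweep(dm, 2, c(5, -3, 2), `+`), rep("RV0", 20),
                        paste0("p", 1:20))
  ssh <- per_axis_statistics(dsh)
  expect_equal(s$sd_mm[s$axis != "norm"], ssh$sd_mm[ssh$axis != "norm"],
               tolerance = 1e-12)
  # rotate all delta vectors by a common rotation
  R <- subvolreg:::versor_to_matrix(versor_from_axis_angle(c(1, 2, 3), 40))
  drot <- make_distances(dm %*% t(R), rep("RV0", 20), paste0("p", 1:20))
  srot <- per_axis_statistics(drot)
  expect_equal(srot$mean_mm[srot$axis == "norm"],
               s$mean_mm[s$axis == "norm"], tolerance = 1e-12)
  expect_equal(srot$sd_mm[srot$axis == "norm"],
               s$sd_mm[s$axis == "norm"], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(srot$sd_mm[srot$axis == "AP"],
                                s$sd_mm[s$axis == "AP"])))
})

test_that("improvement table reproduces hand-computed summaries", {
  # equal norms -> all statistics zero
  deltas <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 2, 0))
  d <- make_distances(deltas, c("full", "RV0", "full", "RV0"),
                      c("p1", "p1", "p2", "p2"))
  it <- improvement_table(d)
  expect_equal(c(it$min_mm, it$max_mm, it$median_mm, it$mean_mm),
               rep(0, 4))
  # improvements {-1, 0, 3} -> min -1, max 3, median 0, mean 2/3
  full_norms <- c(2, 3, 6)
  rv_norms <- c(3, 3, 3)
  d2 <- make_distances(
    rbind(cbind(full_norms, 0, 0), cbind(rv_norms, 0, 0)),
    rep(c("full", "RV0"), each = 3), rep(paste0("p", 1:3), 2))
  it2 <- improvement_table(d2)
  expect_equal(it2$min_mm, -1)
  expect_equal(it2$max_mm, 3)
  expect_equal(it2$median_mm, 0)
  expect_equal(it2$mean_mm, 2 / 3)
  # mean improvement identity: mean(full) - mean(RV)
  expect_equal(it2$mean_mm, mean(full_norms) - mean(rv_norms))
  # missing pairing is an error
  expect_error(improvement_table(d2[-1, ]), "unpaired registration")
})

test_that("improvement table matches brute-force recomputation on study output", {
  set.seed(65)
  n <- 12
  vols <- rep(c("full", "RV0", "RV1"), each = n)
  dm <- matrix(rnorm(3 * n * 3, 0, 2), 3 * n, 3)
  d <- make_distances(dm, vols, rep(paste0("p", 1:n), 3))
  it <- improvement_table(d)
  nrm <- sqrt(rowSums(dm^2))
  for (v in c("RV0", "RV1")) {
    imp <- nrm[vols == "full"] - nrm[vols == v]
    row <- it[it$registration_volume == v, ]
    expect_equal(c(row$min_mm, row$max_mm, row$median_mm, row$mean_mm),
                 c(min(imp), max(imp), median(imp), mean(imp)),
                 tolerance = 1e-12)
  }
})

test_that("F-test handles the equal-variance case and known ratios", {
  x <- rnorm(20)
  ft <- variance_f_test(x, x)
  expect_equal(ft$statistic, 1)
  expect_equal(ft$p_value, 0.5)  # equal df: P(F >= 1) is exactly 1/2
  # SDs 5.2 vs 1.3 at n = 30 each: F = 16 on (29, 29) df, p << 0.001
  a <- rnorm(30); a <- a / sd(a) * 5.2
  b <- rnorm(30); b <- b / sd(b) * 1.3
  ft2 <- variance_f_test(a, b)
  expect_equal(ft2$statistic, 16, tolerance = 1e-12)
  expect_equal(ft2$df1, 29)
  expect_lt(ft2$p_value, 0.001)
})

test_that("F-test agrees with var.test and with numeric CDF integration", {
  set.seed(66)
  a <- rnorm(25, 0, 3)
  b <- rnorm(18, 0, 1.5)
  ft <- variance_f_test(a, b)
  vt <- stats::var.test(a, b, alternative = "greater")
  expect_equal(ft$statistic, unname(vt$statistic), tolerance = 1e-12)
  expect_equal(ft$p_value, vt$p.value, tolerance = 1e-12)
  num <- stats::integrate(function(x) stats::df(x, 24, 17),
                          ft$statistic, Inf, rel.tol = 1e-10)
  expect_equal(ft$p_value, num$value, tolerance = 1e-7)
  # reciprocity: F(a,b) = 1 / F(b,a) with swapped df
  ft_rev <- variance_f_test(b, a)
  expect_equal(ft_rev$statistic, 1 / ft$statistic, tolerance = 1e-12)
  expect_equal(c(ft_rev$df1, ft_rev$df2), c(ft$df2, ft$df1))
  expect_error(variance_f_test(a, rep(2, 5)), "degenerate sample")
  expect_error(variance_f_test(a, 1), "n >= 2")
})

test_that("best-volume frequencies follow the per-pair argmin with ties to the smaller volume", {
  # RV0 always smallest
  n <- 5
  vols <- rep(c("RV0", "RV1", "full"), each = n)
  nrm <- c(rep(0.5, n), rep(1, n), rep(2, n))
  d <- make_distances(cbind(nrm, 0, 0), vols, rep(paste0("p", 1:n), 3))
  bf <- best_volume_frequency(d)
  expect_equal(bf$fraction[bf$registration_volume == "RV0"], 1)
  expect_equal(sum(bf$fraction), 1)
  # exhaustive argmin on random norms
  set.seed(67)
  nrm2 <- runif(3 * n, 0, 5)
  d2 <- make_distances(cbind(nrm2, 0, 0), vols, rep(paste0("p", 1:n), 3))
  bf2 <- best_volume_frequency(d2)
  win <- vapply(paste0("p", 1:n), function(pid) {
    g <- d2[d2$pair_id == pid, ]
    g$registration_volume[which.min(g$norm_mm)]
  }, character(1))
  for (v in unique(vols))
    expect_equal(bf2$n_best[bf2$registration_volume == v],
                 sum(win == v))
  # a tie goes to the smaller registration volume, deterministically
  d3 <- make_distances(cbind(c(1, 1, 1), 0, 0), c("RV1", "RV0", "full"),
                       rep("p1", 3))
  bf3 <- best_volume_frequency(d3)
  expect_equal(bf3$n_best[bf3$registration_volume == "RV0"], 1L)
  expect_error(best_volume_frequency(d2[-1, ]), "incomplete pair")
})
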