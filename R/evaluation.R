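#' Centre-of-mass distance after registration
#'
#' The study's precision measure for one registered image pair: the signed
#' vector from the registered position of the reference prostate's centre of
#' mass to the centre of mass of the prostate delineated on the target
#' series, `delta = COM(target) - T(COM(reference))`, componentwise in
#' (RL, AP, CC) mm. Clinically this is the residual couch-shift error.
#'
#' @param result a `registration_result` from [register_rigid()], or a bare
#'   [rigid_transform()].
#' @param prostate_ref non-empty prostate [binary_mask()] on the reference
#'   (moving) series.
#' @param prostate_target non-empty prostate [binary_mask()] on the target
#'   (fixed) series.
#' @param pair_id label for the image pair.
#' @param registration_volume label of the registration volume used
#'   (`"full"`, `"RV0"`, `"RV1"`, ...).
#' @return A one-row tibble: `pair_id`, `registration_volume`,
#'   `delta_rl_mm`, `delta_ap_mm`, `delta_cc_mm`, `norm_mm`.
#' @export
com_distance <- function(result, prostate_ref, prostate_target,
                         pair_id = NA_character_,
                         registration_volume = NA_character_) {
  transform <- if (inherits(result, "registration_result")) result$transform
               else result
  stopifnot(inherits(transform, "rigid_transform"))
  com_ref <- mask_center_of_mass(prostate_ref)
  com_target <- mask_center_of_mass(prostate_target)
  delta <- com_target - transform_point(transform, com_ref)
  tibble::tibble(
    pair_id = pair_id,
    registration_volume = registration_volume,
    delta_rl_mm = delta[[1]], delta_ap_mm = delta[[2]],
    delta_cc_mm = delta[[3]],
    norm_mm = sqrt(sum(delta^2))
  )
}

delta_cols <- c(RL = "delta_rl_mm", AP = "delta_ap_mm", CC = "delta_cc_mm",
                norm = "norm_mm")

#' Per-axis precision statistics of COM distances
#'
#' Sample mean and sample SD (n - 1 denominator) of each signed component
#' (RL, AP, CC) and of the vector norm, grouped by registration volume. The
#' SD of the signed components is the registration precision per couch axis.
#'
#' @param distances a tibble of [com_distance()] rows (at least 2 pairs per
#'   registration volume).
#' @return A tibble: `registration_volume`, `axis` (RL/AP/CC/norm),
#'   `mean_mm`, `sd_mm`, `n`.
#' @export
per_axis_statistics <- function(distances) {
  check_distances(distances)
  long <- tidyr::pivot_longer(distances, cols = dplyr::all_of(unname(delta_cols)),
                              names_to = "axis", values_to = "value")
  long$axis <- names(delta_cols)[match(long$axis, delta_cols)]
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$registration_volume, .data$axis),
    mean_mm = mean(.data$value), sd_mm = sd(.data$value),
    n = dplyr::n(), .groups = "drop")
  if (any(out$n < 2))
    abort("insufficient pairs")
  out$axis <- factor(out$axis, levels = names(delta_cols))
  dplyr::arrange(out, .data$registration_volume, .data$axis)
}

#' Norm-improvement table versus full-volume registration
#'
#' For each subvolume registration volume, the per-pair improvement of the
#' COM-distance norm over the full-volume registration,
#' `improvement = norm_full - norm_RV` (positive = subvolume better),
#' summarised as min / max / median / mean, together with the one-sided
#' F-test p-value for variance reduction of the norm relative to
#' full-volume registration.
#'
#' @param distances a tibble of [com_distance()] rows containing a
#'   `reference` entry and at least one other registration volume for every
#'   pair.
#' @param reference label of the reference registration volume
#'   (default `"full"`).
#' @return A tibble: `registration_volume`, `min_mm`, `max_mm`, `median_mm`,
#'   `mean_mm`, `p_value`, `n`.
#' @export
improvement_table <- function(distances, reference = "full") {
  check_distances(distances)
  ref <- dplyr::filter(distances, .data$registration_volume == reference)
  oth <- dplyr::filter(distances, .data$registration_volume != reference)
  if (nrow(ref) == 0 || nrow(oth) == 0)
    abort("unpaired registration")
  joined <- dplyr::inner_join(
    dplyr::select(oth, "pair_id", "registration_volume", "norm_mm"),
    dplyr::select(ref, "pair_id", norm_ref = "norm_mm"),
    by = "pair_id")
  counts <- dplyr::count(oth, .data$registration_volume)
  if (nrow(joined) != nrow(oth) || any(counts$n != nrow(ref)))
    abort("unpaired registration")
  joined$improvement <- joined$norm_ref - joined$norm_mm
  dplyr::summarise(
    dplyr::group_by(joined, .data$registration_volume),
    min_mm = min(.data$improvement), max_mm = max(.data$improvement),
    median_mm = median(.data$improvement), mean_mm = mean(.data$improvement),
    p_value = tryCatch(
      variance_f_test(.data$norm_ref, .data$norm_mm)$p_value,
      error = function(e) NA_real_),  # degenerate variances -> no test
    n = dplyr::n(), .groups = "drop")
}

#' One-sided F-test for variance reduction
#'
#' `F = var(sample_a) / var(sample_b)` on `(n_a - 1, n_b - 1)` degrees of
#' freedom with the one-sided p-value `P(F >= F_observed)`, testing whether
#' `sample_a` has larger variance than `sample_b`. By convention the caller
#' puts the condition expected to have the larger variance (e.g. full-volume
#' registration) first.
#'
#' @param sample_a,sample_b numeric vectors with at least 2 values each;
#'   `sample_b` must not have zero variance.
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p_value`.
#' @examples
#' a <- rnorm(30); a <- a / sd(a) * 5.2
#' b <- rnorm(30); b <- b / sd(b) * 1.3
#' variance_f_test(a, b)   # F = 16, p << 0.001
#' @export
variance_f_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    abort("each sample needs n >= 2")
  va <- var(sample_a)
  vb <- var(sample_b)
  if (vb == 0)
    abort("degenerate sample")
  f <- va / vb
  df1 <- length(sample_a) - 1
  df2 <- length(sample_b) - 1
  tibble::tibble(statistic = f, df1 = df1, df2 = df2,
                 p_value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Frequency with which each registration volume is the most precise
#'
#' For every image pair, the registration volume achieving the smallest
#' COM-distance norm receives one count; ties are broken towards the
#' smallest physical registration volume (RV0 first, full volume last).
#'
#' @param distances a tibble of [com_distance()] rows in which every pair
#'   has an entry for every registration volume present.
#' @return A tibble: `registration_volume`, `n_best`, `fraction` (fractions
#'   sum to 1).
#' @export
best_volume_frequency <- function(distances) {
  check_distances(distances)
  vols <- sort(unique(distances$registration_volume))
  lev <- intersect(rv_levels(sum(grepl("^RV", vols))), vols)
  lev <- c(lev, setdiff(vols, lev))
  complete <- dplyr::count(distances, .data$pair_id)
  if (any(complete$n != length(lev)))
    abort("incomplete pair")
  d <- dplyr::mutate(distances,
                     registration_volume = factor(.data$registration_volume,
                                                  levels = lev))
  best <- dplyr::slice_min(
    dplyr::group_by(dplyr::arrange(d, .data$pair_id, .data$registration_volume),
                    .data$pair_id),
    order_by = .data$norm_mm, n = 1, with_ties = FALSE)
  tab <- table(best$registration_volume)
  tibble::tibble(registration_volume = names(tab),
                 n_best = as.integer(tab),
                 fraction = as.numeric(tab) / sum(tab))
}

check_distances <- function(distances) {
  need <- c("pair_id", "registration_volume", unname(delta_cols))
  if (!is.data.frame(distances) || !all(need %in% names(distances)))
    abort("`distances` must contain com_distance() columns")
  invisible(NULL)
}
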