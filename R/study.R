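#' Configuration of a full registration-precision study
#'
#' Describes the whole experiment: how many synthetic patients, the phantom
#' settings shared by all of them (each patient gets its own sub-seed), the
#' margin expansions defining RV1..RVn from the delineated prostate RV0,
#' whether the full-grid registration volume is included, and the optimiser
#' settings. The defaults reproduce the design of a ten-patient, four-series
#' study with registration volumes {full, RV0, RV1, RV2, RV3}, i.e.
#' 10 x 3 x 5 = 150 registrations.
#'
#' @param n_patients number of patients (>= 1).
#' @param phantom a [phantom_config()]; its seed is replaced per patient by
#'   a sub-seed drawn from `seed`.
#' @param margins_mm strictly increasing non-negative margins (mm) defining
#'   RV1..RVn from RV0; default `c(10, 20, 30)`.
#' @param include_full_volume include the full-grid registration volume.
#' @param optimizer an [optimizer_config()].
#' @param seed integer master seed of the study.
#' @param output_dir optional directory; when given, `run_study()` persists
#'   `report.json`, `distances.csv`, `table1.csv`, `figure2.png` and
#'   per-registration transform JSONs there.
#' @param full_volume_stride metric sampling stride for the full-grid
#'   registration volume (see [register_rigid()]); masked volumes always use
#'   every voxel.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_patients = 10L, phantom = phantom_config(),
                         margins_mm = c(10, 20, 30),
                         include_full_volume = TRUE,
                         optimizer = optimizer_config(),
                         seed = 1L, output_dir = NULL,
                         full_volume_stride = 2L) {
  stopifnot(n_patients >= 1L, inherits(phantom, "phantom_config"),
            inherits(optimizer, "optimizer_config"),
            full_volume_stride >= 1L)
  margins_mm <- as.numeric(margins_mm)
  if (length(margins_mm) > 0 &&
      (any(margins_mm < 0) || any(diff(margins_mm) <= 0)))
    abort("`margins_mm` must be non-negative and strictly increasing")
  structure(
    list(n_patients = as.integer(n_patients), phantom = phantom,
         margins_mm = margins_mm,
         include_full_volume = isTRUE(include_full_volume),
         optimizer = optimizer, seed = as.integer(seed),
         output_dir = output_dir,
         full_volume_stride = as.integer(full_volume_stride)),
    class = "study_config"
  )
}

#' Run the full registration-precision study
#'
#' For each patient: generate (or accept) a repeat-MR series, take the
#' reference prostate delineation as RV0, build RV1..RVn by margin
#' expansion, register the reference series to every follow-up under every
#' registration volume, and score every registration by the prostate
#' COM distance. Aggregates per-axis precision statistics, the
#' norm-improvement table versus full-volume registration, one-sided
#' variance F-tests per axis, and the best-volume frequencies. A
#' registration that fails outright is recorded with the identity transform
#' and flagged, and the study continues.
#'
#' @param config a [study_config()].
#' @param patients optional list of pre-built `patient_series` (e.g. from
#'   [load_external_series()]); when given, `n_patients` is taken from its
#'   length and the phantom generator is not used. Each series needs
#'   prostate masks on every series for evaluation.
#' @return A `study_report`: list with tibbles `distances` (one row per
#'   pair x volume, including optimiser diagnostics), `per_axis_stats`,
#'   `improvement`, `f_tests`, `best_volume`, plus `config` and
#'   `n_registrations`. Supports [tidy()], [glance()], [autoplot()].
#' @export
run_study <- function(config, patients = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(patients)) {
    patient_seeds <- local_rng(config$seed,
                               sample.int(2147483646L, config$n_patients))
    patients <- lapply(seq_len(config$n_patients), function(i) {
      cfg <- config$phantom
      cfg$seed <- patient_seeds[i]
      generate_patient(cfg, patient_id = sprintf("patient%02d", i))
    })
  }
  out_dir <- config$output_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list()
  for (p in patients) {
    ref_vol <- p$volumes[[1]]
    rv0 <- p$prostate_masks[[1]]
    vols <- list(RV0 = rv0)
    for (i in seq_along(config$margins_mm))
      vols[[paste0("RV", i)]] <- expand_mask(rv0, config$margins_mm[i])
    if (config$include_full_volume)
      vols$full <- full_volume_mask(ref_vol)
    for (k in seq_along(p$volumes)[-1]) {
      pair_id <- sprintf("%s_pair%d", p$patient_id, k - 1)
      for (vn in names(vols)) {
        stride <- if (vn == "full") config$full_volume_stride else 1L
        res <- tryCatch(
          register_rigid(p$volumes[[k]], ref_vol, vols[[vn]],
                         opt = config$optimizer, stride = stride),
          error = function(e) {
            message(sprintf("registration failed (%s, %s): %s",
                            pair_id, vn, conditionMessage(e)))
            structure(
              list(transform = rigid_transform(center_mm =
                     mask_center_of_mass(rv0)),
                   final_metric = NA_real_, iterations = 0L,
                   converged = FALSE, metric_trace = numeric(0),
                   flagged = TRUE, in_bounds_fraction = NA_real_,
                   n_voxels = sum(vols[[vn]]$data)),
              class = "registration_result")
          })
        cd <- com_distance(res, rv0, p$prostate_masks[[k]],
                           pair_id = pair_id, registration_volume = vn)
        cd$patient_id <- p$patient_id
        cd$final_metric <- res$final_metric
        cd$iterations <- res$iterations
        cd$converged <- res$converged
        cd$flagged <- res$flagged
        rows[[length(rows) + 1L]] <- cd
        if (!is.null(out_dir))
          write_transform(res$transform,
                          file.path(out_dir,
                                    sprintf("transform_%s_%s.json", pair_id, vn)))
      }
    }
  }
  distances <- dplyr::bind_rows(rows)
  lev <- intersect(rv_levels(length(config$margins_mm)),
                   unique(distances$registration_volume))
  distances$registration_volume <- factor(distances$registration_volume,
                                          levels = lev)

  # aggregate layers need >= 2 pairs per group; a minimal study still returns
  # its raw distances with the aggregates absent
  maybe <- function(x) tryCatch(x, error = function(e) NULL)
  report <- structure(
    list(distances = distances,
         per_axis_stats = maybe(per_axis_statistics(distances)),
         improvement = if (config$include_full_volume)
           maybe(improvement_table(distances)) else NULL,
         f_tests = if (config$include_full_volume)
           maybe(study_f_tests(distances)) else NULL,
         best_volume = best_volume_frequency(distances),
         config = config,
         n_registrations = nrow(distances)),
    class = "study_report"
  )
  if (!is.null(out_dir))
    persist_report(report, out_dir)
  report
}

# One-sided F-tests of variance (full-volume variance over subvolume
# variance) per signed axis and for the norm, for each subvolume.
study_f_tests <- function(distances, reference = "full") {
  ref <- dplyr::filter(distances, .data$registration_volume == reference)
  oth <- dplyr::filter(distances, .data$registration_volume != reference)
  purrr::map_dfr(
    split(oth, droplevels(oth$registration_volume)),
    function(g) {
      purrr::map_dfr(names(delta_cols), function(axn) {
        ft <- variance_f_test(ref[[delta_cols[[axn]]]], g[[delta_cols[[axn]]]])
        dplyr::mutate(ft,
                      registration_volume = as.character(
                        g$registration_volume[1]),
                      axis = axn, .before = 1)
      })
    })
}

persist_report <- function(report, out_dir) {
  utils::write.csv(report$distances, file.path(out_dir, "distances.csv"),
                   row.names = FALSE)
  if (!is.null(report$improvement))
    utils::write.csv(report$improvement, file.path(out_dir, "table1.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(n_registrations = report$n_registrations,
         seed = report$config$seed,
         margins_mm = report$config$margins_mm,
         per_axis_stats = report$per_axis_stats,
         improvement = report$improvement,
         f_tests = report$f_tests,
         best_volume = report$best_volume),
    file.path(out_dir, "report.json"),
    digits = NA, auto_unbox = TRUE, dataframe = "rows")
  ggplot2::ggsave(file.path(out_dir, "figure2.png"), autoplot(report),
                  width = 7, height = 4.5, dpi = 150)
  invisible(out_dir)
}

#' Load a repeat-MR patient series from a directory
#'
#' Reads `volume_XX.nii.gz` (>= 2), `prostate_mask_XX.nii.gz` (the reference
#' mask `prostate_mask_00` is required; follow-up masks are optional and
#' only needed for evaluation) and optional ground-truth `transform_XX.json`
#' files, as written by [write_patient_series()]. Follow-up volumes whose
#' grid differs from the reference are resampled onto the reference grid
#' (trilinear), or rejected when `strict = TRUE`.
#'
#' @param dir directory path.
#' @param strict reject geometry mismatches instead of resampling.
#' @param patient_id label; defaults to the directory name.
#' @return A `patient_series`; missing ground-truth transforms are `NULL`
#'   entries, missing follow-up masks are `NULL` entries.
#' @export
load_external_series <- function(dir, strict = FALSE,
                                 patient_id = basename(dir)) {
  vol_files <- sort(list.files(dir, pattern = "^volume_\\d+\\.nii(\\.gz)?$",
                               full.names = TRUE))
  if (length(vol_files) < 2)
    abort("need at least two series")
  tags <- sub("^volume_(\\d+)\\.nii(\\.gz)?$", "\\1", basename(vol_files))
  volumes <- lapply(vol_files, read_volume)
  ref <- volumes[[1]]
  masks <- vector("list", length(volumes))
  transforms <- vector("list", length(volumes))
  for (i in seq_along(volumes)) {
    if (i > 1 && !same_geometry(volumes[[i]], ref)) {
      if (strict)
        abort(sprintf("series %s geometry differs from reference", tags[i]))
      volumes[[i]] <- resample_volume(volumes[[i]], rigid_transform(),
                                      target = ref)
    }
    mf <- file.path(dir, paste0("prostate_mask_", tags[i], ".nii.gz"))
    if (!file.exists(mf))
      mf <- file.path(dir, paste0("prostate_mask_", tags[i], ".nii"))
    if (file.exists(mf)) {
      m <- read_mask(mf)
      if (!same_geometry(m, ref)) {
        if (strict)
          abort(sprintf("mask %s geometry differs from reference", tags[i]))
        mv <- resample_volume(
          image_volume(array(as.double(m$data), dim(m$data)),
                       m$spacing_mm, m$origin_mm),
          rigid_transform(), target = ref)
        m <- binary_mask(mv$data > 0.5, ref$spacing_mm, ref$origin_mm)
      }
      masks[[i]] <- m
    }
    tf <- file.path(dir, paste0("transform_", tags[i], ".json"))
    if (file.exists(tf)) transforms[[i]] <- read_transform(tf)
  }
  if (is.null(masks[[1]]))
    abort("reference prostate mask (prostate_mask_00) is required")
  structure(
    list(volumes = volumes, prostate_masks = masks,
         true_prostate_transforms = transforms,
         patient_id = patient_id,
         prostate_center_mm = unname(mask_center_of_mass(masks[[1]]))),
    class = "patient_series"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", x$n_registrations, " registrations, ",
      length(unique(x$distances$patient_id)), " patients\n", sep = "")
  if (!is.null(x$per_axis_stats)) {
    ap <- dplyr::filter(x$per_axis_stats, .data$axis == "AP")
    for (i in seq_len(nrow(ap)))
      cat(sprintf("  AP SD %-5s %6.2f mm (n = %d)\n",
                  as.character(ap$registration_volume[i]), ap$sd_mm[i], ap$n[i]))
  }
  bv <- x$best_volume
  best <- bv$registration_volume[which.max(bv$fraction)]
  cat(sprintf("  most precise volume: %s for %.0f%% of pairs\n",
              best, 100 * max(bv$fraction)))
  cat(sprintf("  flagged registrations: %d\n", sum(x$distances$flagged)))
  invisible(x)
}

#' @rdname run_study
#' @param x,object a `study_report`.
#' @param ... unused.
#' @export
tidy.study_report <- function(x, ...) {
  x$distances
}

#' @rdname run_study
#' @export
glance.study_report <- function(x, ...) {
  stats <- x$per_axis_stats
  pick <- function(vol, ax) {
    if (is.null(stats)) return(NA_real_)
    v <- stats$sd_mm[stats$registration_volume == vol & stats$axis == ax]
    if (length(v) == 1) v else NA_real_
  }
  bv <- x$best_volume
  rv0 <- dplyr::filter(bv, .data$registration_volume == "RV0")
  tibble::tibble(
    n_registrations = x$n_registrations,
    n_patients = length(unique(x$distances$patient_id)),
    n_converged = sum(x$distances$converged),
    n_flagged = sum(x$distances$flagged),
    sd_ap_full_mm = pick("full", "AP"),
    sd_ap_rv0_mm = pick("RV0", "AP"),
    sd_norm_full_mm = pick("full", "norm"),
    sd_norm_rv0_mm = pick("RV0", "norm"),
    rv0_best_fraction = if (nrow(rv0) == 1) rv0$fraction else NA_real_
  )
}

#' @rdname run_study
#' @export
autoplot.study_report <- function(object, ...) {
  stats <- object$per_axis_stats
  ggplot2::ggplot(stats,
                  ggplot2::aes(x = .data$axis, y = .data$mean_mm,
                               fill = .data$registration_volume)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.85), width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_mm - .data$sd_mm,
                   ymax = .data$mean_mm + .data$sd_mm),
      position = ggplot2::position_dodge(0.85), width = 0.3) +
    ggplot2::labs(x = "Axis", y = "COM distance, mean ± 1 SD (mm)",
                  fill = "Registration\nvolume") +
    ggplot2::theme_minimal()
}
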