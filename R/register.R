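#' Optimiser settings for regular-step gradient descent
#'
#' Settings of the versor-parametrised regular-step gradient descent used by
#' [register_rigid()]: from the current parameters, step a fixed length
#' against the scaled gradient; every time the gradient direction reverses
#' (negative dot product with the previous direction) shrink the step by
#' `relaxation`; declare convergence when the step falls below
#' `min_step_mm`.
#'
#' @param max_step_mm initial step length (mm in translation space).
#' @param min_step_mm convergence step length (mm).
#' @param relaxation step-shrink factor in (0, 1) applied on direction
#'   reversal.
#' @param max_iterations iteration cap; exhausting it returns
#'   `converged = FALSE` rather than an error.
#' @param rotation_scale dimensionless weight converting versor parameters
#'   into step-comparable units: versor components are weighted
#'   `1/rotation_scale` in step space. The default `NULL` auto-scales from
#'   the registration volume's physical extent (weight = 0.7 x the RMS
#'   radius of the mask about the rotation centre, in mm), the
#'   physical-shift scaling rule: a versor change then moves points near the
#'   mask surface about as far as an equal translation step. A fixed weight
#'   either strands the rotation parameters on small volumes (too heavy) or
#'   destabilises large ones (too light).
#' @param gradient_delta_mm central-difference step for the image gradient
#'   (see [metric_gradient()]).
#' @param min_overlap minimum in-bounds fraction tolerated by the metric.
#' @param flag_metric_threshold QC threshold: a result whose final metric
#'   exceeds it is flagged even when converged. Default `Inf` (flag only
#'   non-convergence).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(max_step_mm = 2, min_step_mm = 0.01,
                             relaxation = 0.5, max_iterations = 400L,
                             rotation_scale = NULL,
                             gradient_delta_mm = 1e-3,
                             min_overlap = 0.5,
                             flag_metric_threshold = Inf) {
  stopifnot(min_step_mm > 0, min_step_mm <= max_step_mm,
            relaxation > 0, relaxation < 1, max_iterations >= 1,
            is.null(rotation_scale) || rotation_scale > 0,
            gradient_delta_mm > 0)
  structure(
    list(max_step_mm = max_step_mm, min_step_mm = min_step_mm,
         relaxation = relaxation, max_iterations = as.integer(max_iterations),
         rotation_scale = rotation_scale,
         gradient_delta_mm = gradient_delta_mm,
         min_overlap = min_overlap,
         flag_metric_threshold = flag_metric_threshold),
    class = "optimizer_config"
  )
}

#' Rigid registration with a mask-restricted mean-square metric
#'
#' Registers the moving (reference, pre-treatment) series to the fixed
#' (follow-up) series, with the metric evaluated only over the registration
#' volume `mask` defined in moving space. Optimisation is regular-step
#' gradient descent over the six rigid parameters (versor vector part and
#' translation) about a fixed rotation centre (the mask's centre of mass by
#' default). The best-visited iterate is returned, so the final metric never
#' exceeds the initial one.
#'
#' @inheritParams masked_mean_squares
#' @param opt an [optimizer_config()].
#' @param center_mm rotation centre; defaults to the mask centre of mass.
#' @param init optional initial [rigid_transform()] (re-expressed about
#'   `center_mm`); identity by default.
#' @param com_init if `TRUE`, initialise the translation with the difference
#'   of the intensity centres of mass of fixed and moving.
#' @param stride deterministic metric sampling density: use every
#'   `stride`-th voxel per axis of the mask (1 = every voxel). Useful for
#'   the full-grid registration volume.
#' @return A `registration_result`: list with `transform`, `final_metric`,
#'   `iterations`, `converged`, `metric_trace`, `flagged`,
#'   `in_bounds_fraction` and `n_voxels`.
#' @export
register_rigid <- function(fixed, moving, mask, opt = optimizer_config(),
                           center_mm = NULL, init = NULL, com_init = FALSE,
                           stride = 1L) {
  check_metric_inputs(fixed, moving, mask, rigid_transform())
  stopifnot(inherits(opt, "optimizer_config"), stride >= 1L)
  ind <- which(mask$data, arr.ind = TRUE)
  if (stride > 1L) {
    keep <- (ind[, 1] - 1L) %% stride == 0L &
            (ind[, 2] - 1L) %% stride == 0L &
            (ind[, 3] - 1L) %% stride == 0L
    if (!any(keep))
      abort("stride leaves no mask voxels")
    ind <- ind[keep, , drop = FALSE]
  }
  pts <- sweep(sweep(ind - 1, 2, mask$spacing_mm, `*`), 2, mask$origin_mm, `+`)
  mvals <- moving$data[ind]
  center <- center_mm %||% colMeans(pts)

  p <- numeric(6)
  if (com_init)
    p[4:6] <- intensity_com(fixed) - intensity_com(moving)
  if (!is.null(init))
    p <- transform_to_params(transform_rebase(init, center))

  rot_weight <- if (is.null(opt$rotation_scale)) {
    0.7 * sqrt(mean(rowSums(sweep(pts, 2, center)^2)))
  } else {
    1 / opt$rotation_scale
  }
  scales <- c(rep(rot_weight, 3), 1, 1, 1)
  step <- opt$max_step_mm
  prev_h <- NULL
  trace <- numeric(0)
  best_p <- p
  best_m <- Inf
  converged <- FALSE
  it <- 0L
  while (it < opt$max_iterations) {
    it <- it + 1L
    g <- grad_at(fixed, pts, mvals, params_to_transform(p, center),
                 opt$gradient_delta_mm, opt$min_overlap)
    m <- attr(g, "metric")
    trace[it] <- m
    if (m < best_m) {
      best_m <- m
      best_p <- p
    }
    h <- as.numeric(g) / scales
    gn <- sqrt(sum(h^2))
    if (gn < 1e-12) {
      converged <- TRUE
      break
    }
    if (!is.null(prev_h) && sum(h * prev_h) < 0)
      step <- step * opt$relaxation
    if (step < opt$min_step_mm) {
      converged <- TRUE
      break
    }
    p <- p - step * h / (gn * scales)
    n2 <- sum(p[1:3]^2)
    if (n2 > 0.9)  # keep versor well inside the unit ball
      p[1:3] <- p[1:3] * sqrt(0.9 / n2)
    prev_h <- h
  }

  final <- masked_mean_squares_at(fixed, pts, mvals,
                                  params_to_transform(best_p, center),
                                  opt$min_overlap)
  flagged <- !converged || final$metric > opt$flag_metric_threshold
  structure(
    list(transform = params_to_transform(best_p, center),
         final_metric = final$metric,
         iterations = it,
         converged = converged,
         metric_trace = trace,
         flagged = flagged,
         in_bounds_fraction = final$frac,
         n_voxels = nrow(pts)),
    class = "registration_result"
  )
}

masked_mean_squares_at <- function(fixed, pts, mvals, transform, min_overlap) {
  res <- cpp_masked_msq(fixed$data, dim(fixed$data), fixed$spacing_mm,
                        fixed$origin_mm, pts, mvals,
                        versor_to_matrix(transform$versor),
                        transform$center_mm, transform$translation_mm)
  frac <- res$n_in / res$n_total
  if (frac < min_overlap)
    abort("mask mapped outside overlap")
  list(metric = res$metric, frac = frac)
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result> ",
      if (x$converged) "converged" else "NOT converged",
      if (x$flagged) " [flagged]" else "",
      " after ", x$iterations, " iterations\n", sep = "")
  cat("  final metric ", signif(x$final_metric, 5),
      " over ", x$n_voxels, " mask voxels (in-bounds fraction ",
      signif(x$in_bounds_fraction, 3), ")\n", sep = "")
  print(x$transform)
  invisible(x)
}

#' Plot the metric trace of a registration
#'
#' @param object a `registration_result`.
#' @param ... unused.
#' @return A ggplot of the mean-square metric against iteration.
#' @export
autoplot.registration_result <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$metric_trace),
                       metric = object$metric_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Iteration", y = "Mean-square metric") +
    ggplot2::theme_minimal()
}
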