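#' Mask-restricted mean-square intensity metric
#'
#' The registration cost: the mean of squared intensity differences
#' `(moving(x) - fixed(T x))^2` over the true voxels `x` of a registration
#' volume defined in the *moving* image's space. Only voxels whose mapped
#' point `T x` falls inside the fixed grid contribute; the divisor is the
#' number of contributing voxels. Appropriate for single-modality (MR-MR)
#' registration, where identical anatomy has identical intensity.
#'
#' @param fixed the fixed [image_volume()] (a follow-up series).
#' @param moving the moving [image_volume()] (the reference series; the mask
#'   must share its geometry).
#' @param mask a non-empty [binary_mask()] in moving space.
#' @param transform the [rigid_transform()] mapping moving-space points into
#'   fixed space.
#' @param min_overlap minimum allowed fraction of mask voxels whose mapped
#'   point is in bounds; below this the metric is meaningless and an error
#'   `"mask mapped outside overlap"` is raised.
#' @return The metric value (intensity squared) with attributes `n` (number
#'   of contributing voxels) and `in_bounds_fraction`.
#' @examples
#' v <- image_volume(array(rnorm(8^3), c(8, 8, 8)), c(2, 2, 2))
#' m <- full_volume_mask(v)
#' masked_mean_squares(v, v, m, rigid_transform())  # 0: self-similarity
#' @export
masked_mean_squares <- function(fixed, moving, mask, transform,
                                min_overlap = 0.5) {
  check_metric_inputs(fixed, moving, mask, transform)
  pts <- mask_world_points(mask)
  mvals <- moving$data[mask$data]
  res <- cpp_masked_msq(fixed$data, dim(fixed$data), fixed$spacing_mm,
                        fixed$origin_mm, pts, mvals,
                        versor_to_matrix(transform$versor),
                        transform$center_mm, transform$translation_mm)
  frac <- res$n_in / res$n_total
  if (frac < min_overlap)
    abort("mask mapped outside overlap")
  structure(res$metric, n = res$n_in, in_bounds_fraction = frac)
}

#' Gradient of the masked mean-square metric
#'
#' Analytic gradient of [masked_mean_squares()] with respect to the six
#' transform parameters (versor vector part `v1 v2 v3`, translation
#' `t_rl t_ap t_cc`), obtained by the chain rule through the rigid mapping
#' and the image gradient of the fixed volume. The image gradient is taken
#' by central differences of the trilinear interpolant in world millimetres
#' (step `delta_mm`). Translation components have units intensity^2 / mm.
#'
#' @inheritParams masked_mean_squares
#' @param delta_mm world-space step (mm) of the central differences.
#' @return Named numeric length-6 gradient with attributes `metric`, `n`
#'   and `in_bounds_fraction`.
#' @export
metric_gradient <- function(fixed, moving, mask, transform,
                            delta_mm = 1e-3, min_overlap = 0.5) {
  check_metric_inputs(fixed, moving, mask, transform)
  pts <- mask_world_points(mask)
  mvals <- moving$data[mask$data]
  grad_at(fixed, pts, mvals, transform, delta_mm, min_overlap)
}

check_metric_inputs <- function(fixed, moving, mask, transform) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"),
            inherits(mask, "binary_mask"),
            inherits(transform, "rigid_transform"))
  if (!same_geometry(mask, moving))
    abort("`mask` must share the moving volume's geometry")
  if (!any(mask$data))
    abort("empty delineation")
  invisible(NULL)
}

# Internal driver shared with the optimiser: metric + gradient for
# precomputed mask points / moving values.
grad_at <- function(fixed, pts, mvals, transform, delta_mm, min_overlap) {
  A <- versor_matrix_derivs(transform$versor)
  res <- cpp_masked_msq_grad(fixed$data, dim(fixed$data), fixed$spacing_mm,
                             fixed$origin_mm, pts, mvals,
                             versor_to_matrix(transform$versor),
                             transform$center_mm, transform$translation_mm,
                             A[[1]], A[[2]], A[[3]], delta_mm)
  frac <- res$n_in / res$n_total
  if (frac < min_overlap)
    abort("mask mapped outside overlap")
  structure(stats::setNames(res$gradient,
                            c("v1", "v2", "v3", "t_rl", "t_ap", "t_cc")),
            metric = res$metric, n = res$n_in, in_bounds_fraction = frac)
}

# dR/dv_k for the parametrisation q = (sqrt(1 - |v|^2), v); central
# differences on the versor-to-matrix map. Valid away from 180-degree
# rotations (w near 0), far beyond the small rotations optimised here.
versor_matrix_derivs <- function(versor, eps = 1e-7) {
  v <- versor[2:4]
  if (1 - sum(v^2) < 1e-4)
    abort("rotation too close to 180 degrees for versor derivatives")
  vmat <- function(v) {
    w <- sqrt(max(0, 1 - sum(v^2)))
    versor_to_matrix(c(w, v))
  }
  lapply(1:3, function(k) {
    vp <- v; vm <- v
    vp[k] <- vp[k] + eps
    vm[k] <- vm[k] - eps
    (vmat(vp) - vmat(vm)) / (2 * eps)
  })
}

# Six free parameters <-> rigid transform about a fixed centre.
params_to_transform <- function(p, center_mm) {
  v <- p[1:3]
  n2 <- sum(v^2)
  if (n2 >= 1) {  # defensive: optimiser clamps long before this
    v <- v * sqrt(0.99 / n2)
    n2 <- 0.99
  }
  rigid_transform(c(sqrt(1 - n2), v), p[4:6], center_mm)
}

transform_to_params <- function(transform) {
  q <- transform$versor
  if (q[1] < 0) q <- -q
  c(q[2:4], transform$translation_mm)
}
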