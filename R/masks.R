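#' Expand a mask by an isotropic world-space margin
#'
#' Builds the margin-expanded registration volumes: an output voxel is true
#' iff its Euclidean distance in millimetres (anisotropic spacing respected)
#' to the nearest true input voxel is at most `margin_mm`. The expansion is
#' clipped at the grid extent. With the delineated prostate as input and
#' margins of 10, 20 and 30 mm this yields RV1, RV2 and RV3 from RV0.
#'
#' @param mask a non-empty [binary_mask()].
#' @param margin_mm margin in mm (`>= 0`); 0 returns the input unchanged.
#' @return A [binary_mask()] on the same grid.
#' @examples
#' m <- binary_mask(array(FALSE, c(9, 9, 9)), c(1, 1, 1))
#' m$data[5, 5, 5] <- TRUE
#' sum(expand_mask(m, 2)$data)  # voxels within a 2 mm ball
#' @export
expand_mask <- function(mask, margin_mm) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.numeric(margin_mm) || length(margin_mm) != 1L || margin_mm < 0)
    abort("`margin_mm` must be a single non-negative number")
  if (!any(mask$data))
    abort("empty delineation")
  if (margin_mm == 0) return(mask)
  d2 <- cpp_edt_sq(mask$data, dim(mask$data), mask$spacing_mm)
  out <- array(d2 <= margin_mm^2 + 1e-9, dim(mask$data))
  binary_mask(out, mask$spacing_mm, mask$origin_mm)
}

#' Full-grid registration volume
#'
#' The mask that is true on every voxel of a volume's grid — the
#' "complete volume" registration condition against which the subvolume
#' masks are compared.
#'
#' @param volume an [image_volume()].
#' @return A [binary_mask()] true everywhere, sharing the volume's geometry.
#' @export
full_volume_mask <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  binary_mask(array(TRUE, dim(volume$data)), volume$spacing_mm,
              volume$origin_mm)
}

#' Centre of mass of a binary mask
#'
#' Unweighted mean of the world coordinates of all true voxels. The distance
#' between prostate-mask centres of mass after registration is the study's
#' precision measure (clinically, the residual couch-shift vector).
#'
#' @param mask a non-empty [binary_mask()].
#' @return Named numeric length-3 vector (RL, AP, CC) in mm.
#' @export
mask_center_of_mass <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data))
    abort("empty delineation")
  pts <- mask_world_points(mask)
  stats::setNames(colMeans(pts), .AXES)
}
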