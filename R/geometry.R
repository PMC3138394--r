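#' 3-D image volume with world geometry
#'
#' A scalar 3-D grid together with its voxel spacing and world origin, the
#' in-memory representation of one MR series. Array axes carry the fixed
#' anatomical meaning x = right-left (RL), y = anterior-posterior (AP),
#' z = cranio-caudal (CC); world coordinates are in millimetres and refer to
#' voxel *centres* (0-based indices), so voxel `(i, j, k)` sits at
#' `origin_mm + c(i, j, k) * spacing_mm`.
#'
#' @param data numeric 3-D array of intensities (at least 2 voxels per axis).
#' @param spacing_mm positive length-3 voxel size in mm (RL, AP, CC).
#' @param origin_mm world position (mm) of voxel `(0, 0, 0)`; defaults to
#'   centring the field of view on the world origin.
#' @return An object of class `image_volume` with fields `data`,
#'   `spacing_mm`, `origin_mm` and `axes`.
#' @examples
#' v <- image_volume(array(0, c(4, 4, 4)), spacing_mm = c(1, 1, 2))
#' v$origin_mm
#' @export
image_volume <- function(data, spacing_mm, origin_mm = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3-D array")
  if (any(dim(data) < 2L))
    abort("each axis needs at least 2 voxels")
  storage.mode(data) <- "double"
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || anyNA(spacing_mm) || any(spacing_mm <= 0))
    abort("`spacing_mm` must be 3 strictly positive values")
  if (is.null(origin_mm))
    origin_mm <- -(dim(data) - 1) * spacing_mm / 2
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || anyNA(origin_mm))
    abort("`origin_mm` must be 3 finite values")
  structure(
    list(data = data, spacing_mm = spacing_mm, origin_mm = origin_mm,
         axes = .AXES),
    class = "image_volume"
  )
}

#' Binary mask sharing an image volume's geometry
#'
#' Boolean 3-D grid used both for delineations (the prostate, RV0) and for
#' registration volumes (margin expansions RV1..RV3, or the full grid). Same
#' geometry conventions as [image_volume()].
#'
#' @param data logical (or 0/1 numeric) 3-D array.
#' @inheritParams image_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing_mm, origin_mm = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3-D array")
  if (any(dim(data) < 2L))
    abort("each axis needs at least 2 voxels")
  if (!is.logical(data)) {
    data <- array(as.numeric(data) > 0.5, dim = dim(data))
  }
  v <- image_volume(array(0, dim(data)), spacing_mm, origin_mm)
  structure(
    list(data = data, spacing_mm = v$spacing_mm, origin_mm = v$origin_mm,
         axes = .AXES),
    class = "binary_mask"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing_mm, 4), collapse = "/"),
      " mm (RL/AP/CC)\n", sep = "")
  cat("  intensity range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing_mm, 4), collapse = "/"),
      " mm, ", sum(x$data), " true voxels\n", sep = "")
  invisible(x)
}

# Shared geometry check (shape, spacing, origin within tolerance).
same_geometry <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

# World coordinates along each axis (voxel centres).
axis_coords <- function(x) {
  d <- dim(x$data)
  lapply(1:3, function(a) x$origin_mm[a] + (seq_len(d[a]) - 1) * x$spacing_mm[a])
}

# n x 3 world coordinates of all TRUE voxels of a mask.
mask_world_points <- function(mask) {
  ind <- which(mask$data, arr.ind = TRUE)
  sweep(sweep(ind - 1, 2, mask$spacing_mm, `*`), 2, mask$origin_mm, `+`)
}

# World bounds of the voxel-centre lattice.
world_bounds <- function(x) {
  d <- dim(x$data)
  rbind(lo = x$origin_mm, hi = x$origin_mm + (d - 1) * x$spacing_mm)
}

#' Trilinear interpolation at world points
#'
#' Samples a volume at arbitrary world-space points by trilinear
#' interpolation of the eight surrounding voxel centres. Points outside the
#' voxel-centre lattice return `NA` (the out-of-bounds marker).
#'
#' @param volume an [image_volume()].
#' @param points_mm a length-3 vector or an n x 3 matrix of world points (mm).
#' @return Numeric vector of interpolated intensities, `NA` out of bounds.
#' @examples
#' v <- image_volume(array(seq_len(27), c(3, 3, 3)), c(1, 1, 1))
#' trilinear_sample(v, c(0, 0, 0))   # centre voxel value
#' @export
trilinear_sample <- function(volume, points_mm) {
  stopifnot(inherits(volume, "image_volume"))
  pts <- if (is.matrix(points_mm)) points_mm else matrix(points_mm, ncol = 3)
  storage.mode(pts) <- "double"
  res <- cpp_trilinear(volume$data, dim(volume$data), volume$spacing_mm,
                       volume$origin_mm, pts)
  res$values
}

# Intensity-weighted centre of mass of a volume (for optional COM
# pre-alignment of the optimiser).
intensity_com <- function(volume) {
  ax <- axis_coords(volume)
  w <- volume$data
  tot <- sum(w)
  c(sum(apply(w, 1, sum) * ax[[1]]),
    sum(apply(w, 2, sum) * ax[[2]]),
    sum(apply(w, 3, sum) * ax[[3]])) / tot
}

#' Resample a volume under a rigid transform
#'
#' Returns the volume transported by `transform`: the output voxel at world
#' point `x` holds `volume` sampled at `transform^-1(x)`. Used to fabricate
#' ground-truth-shifted images and to put external series onto a common grid.
#'
#' @param volume an [image_volume()].
#' @param transform a [rigid_transform()]; identity by default.
#' @param target an [image_volume()] or [binary_mask()] supplying the output
#'   grid geometry; defaults to `volume` itself.
#' @param fill intensity for points mapping outside `volume`.
#' @return An [image_volume()] on the target grid.
#' @export
resample_volume <- function(volume, transform = rigid_transform(),
                            target = volume, fill = 0) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(target$data)
  ax <- axis_coords(target)
  pts <- cbind(rep(ax[[1]], times = d[2] * d[3]),
               rep(rep(ax[[2]], each = d[1]), times = d[3]),
               rep(ax[[3]], each = d[1] * d[2]))
  inv <- transform_invert(transform)
  q <- transform_point(inv, pts)
  vals <- trilinear_sample(volume, q)
  vals[is.na(vals)] <- fill
  image_volume(array(vals, d), target$spacing_mm, target$origin_mm)
}
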