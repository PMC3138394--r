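#' Rigid 3-D transform (versor + translation about a centre)
#'
#' Parametrises a rigid-body mapping as a unit quaternion (versor) rotation
#' about a fixed centre plus a translation:
#' `p' = R(versor) (p - center) + center + translation`. The six free
#' parameters optimised during registration are the three versor vector
#' components and the three translations; the centre is held fixed.
#'
#' @param versor length-4 unit quaternion `(w, x, y, z)`; normalised on
#'   construction (must be within 1e-6 of unit norm).
#' @param translation_mm length-3 translation (mm), axes RL/AP/CC.
#' @param center_mm length-3 rotation centre (mm).
#' @return An object of class `rigid_transform`.
#' @examples
#' t <- rigid_transform(translation_mm = c(1, -2, 0.5))
#' transform_point(t, c(0, 0, 0))
#' @export
rigid_transform <- function(versor = c(1, 0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  versor <- as.numeric(versor)
  if (length(versor) != 4L || anyNA(versor))
    abort("`versor` must be 4 finite values (w, x, y, z)")
  nrm <- sqrt(sum(versor^2))
  if (abs(nrm - 1) > 1e-6)
    abort("`versor` must have unit norm")
  versor <- versor / nrm
  if (versor[1] < 0) versor <- -versor  # canonical hemisphere
  translation_mm <- as.numeric(translation_mm)
  center_mm <- as.numeric(center_mm)
  stopifnot(length(translation_mm) == 3L, length(center_mm) == 3L)
  structure(
    list(versor = versor, translation_mm = translation_mm,
         center_mm = center_mm),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rotation ", signif(rotation_angle_deg(x), 4),
      " deg, translation (", paste(signif(x$translation_mm, 4), collapse = ", "),
      ") mm about centre (", paste(signif(x$center_mm, 4), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Build a versor from an axis and an angle
#'
#' @param axis length-3 rotation axis (need not be unit length).
#' @param angle_deg rotation angle in degrees.
#' @return Length-4 unit quaternion `(w, x, y, z)`.
#' @export
versor_from_axis_angle <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) return(c(1, 0, 0, 0))
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * axis / n)
}

#' Rotation angle of a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle_deg <- function(transform) {
  w <- min(1, abs(transform$versor[1]))
  2 * acos(w) * 180 / pi
}

# Rotation matrix of a unit quaternion (w, x, y, z).
versor_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Unit quaternion (w >= 0) from a rotation matrix (Shepperd's method).
versor_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Apply a rigid transform to world points
#'
#' @param transform a [rigid_transform()].
#' @param points_mm length-3 vector or n x 3 matrix of world points (mm).
#' @return Transformed points in the same shape as the input.
#' @export
transform_point <- function(transform, points_mm) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- !is.matrix(points_mm)
  pts <- if (vec) matrix(as.numeric(points_mm), ncol = 3) else points_mm
  R <- versor_to_matrix(transform$versor)
  out <- sweep(pts, 2, transform$center_mm) %*% t(R)
  out <- sweep(out, 2, transform$center_mm + transform$translation_mm, `+`)
  if (vec) drop(out) else out
}

#' Homogeneous 4 x 4 matrix of a rigid transform
#'
#' @inheritParams transform_point
#' @return A 4 x 4 matrix `M` with `M %*% c(p, 1) = c(transform_point(t, p), 1)`.
#' @export
transform_to_matrix <- function(transform) {
  R <- versor_to_matrix(transform$versor)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- transform$center_mm + transform$translation_mm -
    R %*% transform$center_mm
  M
}

#' Compose two rigid transforms
#'
#' Returns the transform applying `b` first, then `a` (i.e. `a %then% b` in
#' mapping terms: `T(p) = a(b(p))`). The result is expressed about `a`'s
#' rotation centre.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
transform_compose <- function(a, b) {
  M <- transform_to_matrix(a) %*% transform_to_matrix(b)
  Rm <- M[1:3, 1:3]
  q <- versor_from_matrix(Rm)
  ctr <- a$center_mm
  # solve translation so that R (p - c) + c + t reproduces M
  t_mm <- M[1:3, 4] + Rm %*% ctr - ctr
  rigid_transform(q, as.numeric(t_mm), ctr)
}

#' Invert a rigid transform
#'
#' `transform_compose(t, transform_invert(t))` is the identity to within
#' 1e-9 mm.
#'
#' @inheritParams transform_point
#' @return A [rigid_transform()] about the same centre.
#' @export
transform_invert <- function(transform) {
  q <- transform$versor
  qinv <- c(q[1], -q[2:4])
  Rt <- t(versor_to_matrix(q))
  rigid_transform(qinv, as.numeric(-Rt %*% transform$translation_mm),
                  transform$center_mm)
}

# Re-express the same mapping about a different rotation centre.
transform_rebase <- function(transform, center_mm) {
  R <- versor_to_matrix(transform$versor)
  t_new <- as.numeric(R %*% (center_mm - transform$center_mm)) +
    transform$center_mm + transform$translation_mm - center_mm
  rigid_transform(transform$versor, t_new, center_mm)
}

#' Write / read a rigid transform as JSON
#'
#' The JSON dialect `{versor, translation_mm, center_mm}` is shared between
#' phantom ground-truth files and registration results.
#'
#' @param transform a [rigid_transform()].
#' @param path file path.
#' @return `write_transform()` returns `path` invisibly; `read_transform()`
#'   returns a [rigid_transform()].
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(versor = transform$versor,
         translation_mm = transform$translation_mm,
         center_mm = transform$center_mm),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$versor, x$translation_mm, x$center_mm)
}
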