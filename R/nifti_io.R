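#' Read and write volumes and masks as NIfTI-1
#'
#' Volumes are stored with a diagonal RAS affine (qform code 2): spacing on
#' the diagonal, the world position of voxel (0,0,0) in the fourth column.
#' On read, images are reoriented to RAS so that array axes mean x = RL,
#' y = AP, z = CC; oblique (non-axis-aligned) affines are rejected.
#'
#' @param x an [image_volume()] or [binary_mask()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; volumes default to `"float"`, masks
#'   are always written as `"uint8"` with values 0/1.
#' @return Readers return an [image_volume()] / [binary_mask()]; writers
#'   return `path` invisibly.
#' @name nifti_io
NULL

nifti_from <- function(data, spacing_mm, origin_mm) {
  im <- RNifti::asNifti(data)
  RNifti::pixdim(im) <- spacing_mm
  aff <- diag(c(spacing_mm, 1))
  aff[1:3, 4] <- origin_mm
  RNifti::`qform<-`(im, structure(aff, code = 2L))
}

#' @rdname nifti_io
#' @export
write_volume <- function(x, path, datatype = "float") {
  stopifnot(inherits(x, "image_volume"))
  im <- nifti_from(x$data, x$spacing_mm, x$origin_mm)
  RNifti::writeNifti(im, path, datatype = datatype)
  invisible(path)
}

#' @rdname nifti_io
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "binary_mask"))
  im <- nifti_from(array(as.double(x$data), dim(x$data)), x$spacing_mm,
                   x$origin_mm)
  RNifti::writeNifti(im, path, datatype = "uint8")
  invisible(path)
}

read_nifti_geometry <- function(path) {
  im <- RNifti::readNifti(path)
  if (!identical(RNifti::orientation(im), "RAS"))
    RNifti::orientation(im) <- "RAS"
  xf <- RNifti::xform(im)
  rot <- xf[1:3, 1:3]
  offdiag <- rot
  diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-3 * max(abs(diag(rot)))))
    abort("oblique NIfTI orientations are not supported")
  if (length(dim(im)) != 3L)
    abort("expected a 3-D NIfTI image")
  list(data = array(as.numeric(im), dim(im)),
       spacing_mm = abs(diag(rot)),
       origin_mm = xf[1:3, 4])
}

#' @rdname nifti_io
#' @export
read_volume <- function(path) {
  g <- read_nifti_geometry(path)
  image_volume(g$data, g$spacing_mm, g$origin_mm)
}

#' @rdname nifti_io
#' @export
read_mask <- function(path) {
  g <- read_nifti_geometry(path)
  binary_mask(g$data > 0.5, g$spacing_mm, g$origin_mm)
}
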