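#' Configuration of the synthetic pelvic phantom
#'
#' Describes one synthetic "patient": the imaging grid, the number of repeat
#' series, the rigid prostate-motion distribution relative to the fixed bony
#' anatomy, the amplitude of rectum/bladder appearance changes between
#' series, and the MR-magnitude noise level. The `"paper"` grid matches a
#' T2-weighted pelvic acquisition (matrix 384 x 348, 120 slices,
#' 1.17 x 1.17 mm in-plane, 1.7 mm slices); the default `"small"` grid keeps
#' the same field of view at 96 x 96 x 60 voxels for desk-scale runtimes.
#'
#' Motion defaults are anisotropic and AP-dominant (SD 4 mm AP, 2.5 mm CC,
#' 0.5 mm RL, 1 degree rotation), reflecting how the prostate moves against
#' the pelvis with rectal and bladder filling.
#'
#' @param grid `"small"` (96 x 96 x 60) or `"paper"` (384 x 348 x 120);
#'   ignored when `grid_shape` is given.
#' @param grid_shape optional explicit voxels per axis (RL, AP, CC).
#' @param spacing_mm optional per-axis voxel size (mm); by default derived
#'   from `grid_shape` so the field of view stays 449.28 x 407.16 x 204 mm.
#' @param n_series number of repeat series per patient (>= 2; the first is
#'   the reference).
#' @param prostate_motion_sd_mm per-axis SD (RL, AP, CC) of the rigid
#'   prostate displacement relative to bone, in mm.
#' @param prostate_rotation_sd_deg SD of the prostate rotation angle
#'   (degrees) about a random axis through the prostate centre.
#' @param organ_variation_scale dimensionless amplitude of rectum/bladder
#'   appearance change between series (0 = frozen organs; 1 = rectum radius
#'   +-35%, lumen intensity 50 +- 40, bladder size +-20%, rectum/bladder walls
#'   shifting by a few mm as filling changes — partly coupled to the drawn
#'   prostate motion, since filling is what displaces the prostate — and 2%
#'   global intensity drift).
#' @param noise_sigma Rician (MR-magnitude) noise scale in intensity units
#'   (soft tissue is ~90, prostate ~130 on this phantom's scale).
#' @param seed integer seed; the whole patient is deterministic given the
#'   config.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c("small", "paper"), grid_shape = NULL,
                           spacing_mm = NULL, n_series = 4L,
                           prostate_motion_sd_mm = c(rl = 0.5, ap = 4, cc = 2.5),
                           prostate_rotation_sd_deg = 1,
                           organ_variation_scale = 1,
                           noise_sigma = 4,
                           seed = 1L) {
  grid <- match.arg(grid)
  if (is.null(grid_shape))
    grid_shape <- if (grid == "paper") c(384L, 348L, 120L) else c(96L, 96L, 60L)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L))
  if (is.null(spacing_mm))
    spacing_mm <- c(449.28, 407.16, 204) / grid_shape
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    abort("`spacing_mm` must be 3 strictly positive values")
  prostate_motion_sd_mm <- as.numeric(prostate_motion_sd_mm)
  if (length(prostate_motion_sd_mm) == 1L)
    prostate_motion_sd_mm <- rep(prostate_motion_sd_mm, 3)
  stopifnot(length(prostate_motion_sd_mm) == 3L,
            all(prostate_motion_sd_mm >= 0),
            prostate_rotation_sd_deg >= 0,
            organ_variation_scale >= 0, noise_sigma >= 0,
            n_series >= 2L)
  structure(
    list(grid_shape = grid_shape, spacing_mm = spacing_mm,
         n_series = as.integer(n_series),
         prostate_motion_sd_mm = prostate_motion_sd_mm,
         prostate_rotation_sd_deg = prostate_rotation_sd_deg,
         organ_variation_scale = organ_variation_scale,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Generate one synthetic repeat-MR patient
#'
#' Rasterises an analytic pelvic phantom (body outline, iliac/sacral/pubic
#' bone shells with bright marrow, bladder, rectum tube, ellipsoidal
#' prostate with internal texture) with anti-aliased edges, then produces
#' `n_series` repeat volumes: bony anatomy and body outline are identical
#' across series, while the prostate layer is rigidly displaced by a draw
#' from the configured motion distribution, the rectum and bladder change
#' size/intensity, and independent Rician noise is applied. The applied
#' prostate motions are returned exactly, and the per-series prostate masks
#' are the reference delineation transported by those motions.
#'
#' @param config a [phantom_config()].
#' @param patient_id label stored on the result (does not affect the data;
#'   vary `config$seed` to vary anatomy).
#' @return A `patient_series`: lists `volumes`, `prostate_masks`,
#'   `true_prostate_transforms` (index 1 is the reference/identity), plus
#'   `patient_id` and `prostate_center_mm`.
#' @examples
#' p <- generate_patient(phantom_config(grid_shape = c(48, 48, 30),
#'                                      n_series = 2, seed = 7))
#' p$true_prostate_transforms[[2]]
#' @export
generate_patient <- function(config, patient_id = "patient01") {
  stopifnot(inherits(config, "phantom_config"))
  local_rng(config$seed, generate_patient_impl(config, patient_id))
}

generate_patient_impl <- function(config, patient_id) {
  d <- config$grid_shape
  sp <- config$spacing_mm
  org <- -(d - 1) * sp / 2
  n <- config$n_series
  scale <- config$organ_variation_scale

  X <- array(rep(org[1] + (seq_len(d[1]) - 1) * sp[1], times = d[2] * d[3]), d)
  Y <- array(rep(rep(org[2] + (seq_len(d[2]) - 1) * sp[2], each = d[1]),
                 times = d[3]), d)
  Z <- array(rep(org[3] + (seq_len(d[3]) - 1) * sp[3], each = d[1] * d[2]), d)
  ew <- mean(sp)  # anti-aliasing edge width ~ 1 voxel
  clamp01 <- function(t) pmin(pmax(t, 0), 1)
  ell <- function(c3, r3) {
    rr <- sqrt(((X - c3[1]) / r3[1])^2 + ((Y - c3[2]) / r3[2])^2 +
                 ((Z - c3[3]) / r3[3])^2)
    clamp01((1 - rr) * mean(r3) / ew + 0.5)
  }
  paint <- function(I, alpha, value) I * (1 - alpha) + value * alpha

  # ---- patient-level anatomy (drawn once, static across series) ----
  u1 <- function(m = 1) runif(m, -1, 1)
  body_scale <- 1 + 0.04 * u1()
  body_c <- c(0, 10)
  body_r <- c(170, 122) * body_scale
  pc <- c(0, 10, -25) + rnorm(3, 0, 3)          # prostate centre
  pr <- c(20, 18, 19) * (1 + 0.15 * u1(3))      # prostate radii
  rect_base_r <- 13 * (1 + 0.1 * u1())
  rect_c <- c(pc[1], pc[2] + pr[2] + 7 + rect_base_r, pc[3] + 5)
  bladder_c <- c(pc[1], pc[2] - pr[2] - 30, pc[3] + 40)
  bladder_r <- c(42, 34, 36)

  check_prostate_fov(pc, pr, d, sp, org, ew,
                     "grid too small for phantom anatomy")

  static <- array(5, d)  # air baseline
  rrb <- sqrt(((X - body_c[1]) / body_r[1])^2 + ((Y - body_c[2]) / body_r[2])^2)
  ab <- clamp01((1 - rrb) * mean(body_r) / ew + 0.5)
  static <- paint(static, ab, 90)               # soft tissue
  # patient-specific soft-tissue heterogeneity (fat planes, muscle): a smooth
  # random field, fixed across series, ~12 mm correlation length, SD 12
  coarse_d <- pmax(4L, as.integer(ceiling((d - 1) * sp / 12)) + 1L)
  tex_coarse <- image_volume(array(rnorm(prod(coarse_d), 0, 12), coarse_d),
                             spacing_mm = (d - 1) * sp / (coarse_d - 1),
                             origin_mm = org)
  tex <- resample_volume(tex_coarse, target = image_volume(array(0, d), sp, org))
  static <- static + tex$data * ab
  bones <- list(
    list(c(112, 5, 15),  c(34, 62, 82), c(22, 46, 66)),   # right ilium
    list(c(-112, 5, 15), c(34, 62, 82), c(22, 46, 66)),   # left ilium
    list(c(0, 88, 10),   c(40, 30, 58), c(26, 18, 42)),   # sacrum
    list(c(0, -72, -38), c(34, 16, 22), c(24, 9, 14))     # pubis
  )
  for (b in bones) {
    static <- paint(static, ell(b[[1]], b[[2]]), 30)      # cortical shell
    static <- paint(static, ell(b[[1]], b[[3]]), 150)     # marrow
  }

  # ---- per-series draws (fixed order, before any heavy work) ----
  draws <- vector("list", n)
  for (k in seq_len(n)) {
    if (k == 1L) {
      draws[[k]] <- list(t = c(0, 0, 0), versor = c(1, 0, 0, 0),
                         ur = 0, ui = 0, ub = 0, ud = 0,
                         rect_shift = c(0, 0), bladder_shift = c(0, 0),
                         noise_seed = sample.int(2147483646L, 1))
    } else {
      t_k <- rnorm(3, 0, config$prostate_motion_sd_mm)
      axis <- rnorm(3)
      angle <- rnorm(1, 0, config$prostate_rotation_sd_deg)
      draws[[k]] <- list(t = t_k,
                         versor = versor_from_axis_angle(axis, angle),
                         ur = u1(), ui = u1(), ub = u1(), ud = u1(),
                         # organ filling moves the walls (AP/CC shifts, mm);
                         # rectal filling is what pushes the prostate, so the
                         # rectal wall shift tracks the drawn AP motion
                         rect_shift = scale * c(0.8 * t_k[2] + rnorm(1, 0, 1),
                                                rnorm(1, 0, 1)),
                         bladder_shift = scale * c(rnorm(1, 0, 2),
                                                   0.4 * t_k[3] + rnorm(1, 0, 2)),
                         noise_seed = sample.int(2147483646L, 1))
    }
  }

  prostate_value <- function(qx, qy, qz) {
    tex <- 130 + 12 * sin(2 * pi * qx / 23) * sin(2 * pi * qy / 19) *
      sin(2 * pi * qz / 29)
    rrc <- sqrt(((qx - pc[1]) / (pr[1] * 0.45))^2 +
                  ((qy - pc[2]) / (pr[2] * 0.45))^2 +
                  ((qz - pc[3]) / (pr[3] * 0.45))^2)
    acz <- clamp01((1 - rrc) * mean(pr * 0.45) / ew + 0.5)
    tex * (1 - acz) + 108 * acz
  }

  volumes <- vector("list", n)
  masks <- vector("list", n)
  transforms <- vector("list", n)
  for (k in seq_len(n)) {
    dk <- draws[[k]]
    Tk <- rigid_transform(dk$versor, dk$t, pc)
    if (k > 1L)
      check_prostate_fov(pc + dk$t, pr, d, sp, org, ew,
                         "motion exceeds field of view")
    I <- static
    brk <- bladder_r * (1 + 0.2 * scale * dk$ub)
    bck <- bladder_c + c(0, dk$bladder_shift)
    I <- paint(I, ell(bck, brk), 200)
    rrk <- rect_base_r * (1 + 0.35 * scale * dk$ur)
    lum <- 50 + 40 * scale * dk$ui  # gas-dark to near-tissue content
    rck <- rect_c + c(0, dk$rect_shift)
    dxy <- sqrt((X - rck[1])^2 + (Y - rck[2])^2)
    azf <- clamp01((75 - abs(Z - rck[3])) / ew + 0.5)
    I <- paint(I, clamp01(((rrk + 4) - dxy) / ew + 0.5) * azf, 72)
    I <- paint(I, clamp01((rrk - dxy) / ew + 0.5) * azf, lum)
    # prostate layer sampled analytically at Tk^-1(x): no resampling error
    is_identity <- k == 1L || (all(dk$t == 0) && dk$versor[1] == 1)
    if (is_identity) {
      qx <- X; qy <- Y; qz <- Z
    } else {
      Rt <- t(versor_to_matrix(dk$versor))
      xs <- X - pc[1] - dk$t[1]
      ys <- Y - pc[2] - dk$t[2]
      zs <- Z - pc[3] - dk$t[3]
      qx <- Rt[1, 1] * xs + Rt[1, 2] * ys + Rt[1, 3] * zs + pc[1]
      qy <- Rt[2, 1] * xs + Rt[2, 2] * ys + Rt[2, 3] * zs + pc[2]
      qz <- Rt[3, 1] * xs + Rt[3, 2] * ys + Rt[3, 3] * zs + pc[3]
    }
    rrp <- sqrt(((qx - pc[1]) / pr[1])^2 + ((qy - pc[2]) / pr[2])^2 +
                  ((qz - pc[3]) / pr[3])^2)
    ap_ <- clamp01((1 - rrp) * mean(pr) / ew + 0.5)
    # peri-prostatic halo: tissue within ~15 mm of the capsule is dragged
    # along with the gland (partial weight), carrying its texture with it
    ph <- pr + 15
    rrh <- sqrt(((qx - pc[1]) / ph[1])^2 + ((qy - pc[2]) / ph[2])^2 +
                  ((qz - pc[3]) / ph[3])^2)
    ah_ <- 0.4 * clamp01((1 - rrh) * mean(ph) / ew + 0.5)
    if (is_identity) {
      tex_q <- tex$data
    } else {
      tex_q <- trilinear_sample(tex, cbind(as.numeric(qx), as.numeric(qy),
                                           as.numeric(qz)))
      tex_q[is.na(tex_q)] <- 0
      tex_q <- array(tex_q, d)
    }
    a_move <- pmax(ap_, ah_)
    halo_w <- a_move - ap_
    I <- I * (1 - a_move) + prostate_value(qx, qy, qz) * ap_ +
      (90 + tex_q) * halo_w
    I <- I * (1 + 0.02 * scale * dk$ud)         # inter-scan intensity drift
    vol <- image_volume(I, sp, org)
    if (config$noise_sigma > 0)
      vol <- apply_noise(vol, config$noise_sigma, dk$noise_seed)
    volumes[[k]] <- vol
    masks[[k]] <- binary_mask(rrp <= 1, sp, org)
    transforms[[k]] <- Tk
  }

  structure(
    list(volumes = volumes, prostate_masks = masks,
         true_prostate_transforms = transforms,
         patient_id = patient_id, prostate_center_mm = pc),
    class = "patient_series"
  )
}

check_prostate_fov <- function(center, radii, d, sp, org, ew, msg) {
  lo <- org + ew
  hi <- org + (d - 1) * sp - ew
  if (any(center - radii * 1.15 < lo) || any(center + radii * 1.15 > hi))
    abort(msg)
  invisible(NULL)
}

#' @export
print.patient_series <- function(x, ...) {
  cat("<patient_series> ", x$patient_id, ": ", length(x$volumes),
      " series of ", paste(dim(x$volumes[[1]]$data), collapse = " x "),
      " voxels\n", sep = "")
  for (k in seq_along(x$volumes)) {
    tr <- x$true_prostate_transforms[[k]]
    cat(sprintf("  series %d: prostate shift (%s) mm, rotation %.2f deg\n",
                k - 1, paste(sprintf("%.2f", tr$translation_mm), collapse = ", "),
                rotation_angle_deg(tr)))
  }
  invisible(x)
}

#' Apply Rician (MR-magnitude) noise to a volume
#'
#' Each output voxel is the magnitude of the input signal perturbed by
#' complex Gaussian noise: `sqrt((v + n1)^2 + n2^2)` with
#' `n1, n2 ~ N(0, sigma)` — the noise model of magnitude-reconstructed MRI.
#' `sigma = 0` returns the input unchanged.
#'
#' @param volume an [image_volume()].
#' @param sigma noise scale in intensity units (`>= 0`).
#' @param seed optional integer seed; when given, the ambient RNG state is
#'   left untouched.
#' @return An [image_volume()] with the same geometry.
#' @export
apply_noise <- function(volume, sigma, seed = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    abort("`sigma` must be a single non-negative number")
  if (sigma == 0) return(volume)
  noisy <- function() {
    m <- length(volume$data)
    n1 <- rnorm(m, 0, sigma)
    n2 <- rnorm(m, 0, sigma)
    array(sqrt((as.numeric(volume$data) + n1)^2 + n2^2), dim(volume$data))
  }
  out <- if (is.null(seed)) noisy() else local_rng(seed, noisy())
  image_volume(out, volume$spacing_mm, volume$origin_mm)
}

#' Write a patient series to a directory
#'
#' Writes `volume_XX.nii.gz`, `prostate_mask_XX.nii.gz` and
#' `transform_XX.json` (ground-truth prostate motion) for each series,
#' zero-based. The layout round-trips through [load_external_series()].
#'
#' @param series a `patient_series`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patient_series <- function(series, dir) {
  stopifnot(inherits(series, "patient_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(series$volumes)) {
    tag <- sprintf("%02d", k - 1)
    write_volume(series$volumes[[k]], file.path(dir, paste0("volume_", tag, ".nii.gz")))
    write_mask(series$prostate_masks[[k]],
               file.path(dir, paste0("prostate_mask_", tag, ".nii.gz")))
    write_transform(series$true_prostate_transforms[[k]],
                    file.path(dir, paste0("transform_", tag, ".json")))
  }
  invisible(dir)
}

# Evaluate `code` under a private RNG stream, restoring the caller's state.
local_rng <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
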