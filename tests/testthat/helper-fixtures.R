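# Shared fixture builders and independent oracles used across test files.

random_volume <- function(dim = c(8, 8, 8), spacing = c(1, 1, 1),
                          mean = 100, sd = 10) {
  image_volume(array(rnorm(prod(dim), mean, sd), dim), spacing)
}

random_mask <- function(dim, spacing, n_true) {
  m <- array(FALSE, dim)
  m[sample(prod(dim), n_true)] <- TRUE
  binary_mask(m, spacing)
}

# Brute-force trilinear interpolation (independent of the compiled kernel).
tri_oracle <- function(vol, p) {
  d <- dim(vol$data)
  f <- (p - vol$origin_mm) / vol$spacing_mm
  if (any(f < 0 | f > d - 1)) return(NA_real_)
  i0 <- pmin(floor(f), d - 2)
  fr <- f - i0
  s <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
    s <- s + w * vol$data[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  s
}

# World coordinates of all TRUE voxels (duplicated on purpose, as an oracle).
mask_points_oracle <- function(mask) {
  ind <- which(mask$data, arr.ind = TRUE)
  sweep(sweep(ind - 1, 2, mask$spacing_mm, `*`), 2, mask$origin_mm, `+`)
}

# Explicit per-voxel loop for the mask-restricted mean-square metric.
msq_oracle <- function(fixed, moving, mask, transform) {
  pts <- mask_points_oracle(mask)
  mv <- moving$data[mask$data]
  mapped <- transform_point(transform, pts)
  acc <- 0
  n <- 0
  for (i in seq_len(nrow(mapped))) {
    f <- tri_oracle(fixed, mapped[i, ])
    if (!is.na(f)) {
      acc <- acc + (mv[i] - f)^2
      n <- n + 1
    }
  }
  list(metric = acc / n, n = n)
}

# Small phantom settings for quick structural tests (anatomy still fits).
quick_phantom <- function(...) {
  phantom_config(grid_shape = c(64, 64, 40), ...)
}

# The default seeded study is expensive; compute it once per test run and
# share it between the design-count and ordering checks.
.study_cache <- new.env(parent = emptyenv())
default_study_report <- function() {
  if (is.null(.study_cache$report))
    .study_cache$report <- run_study(study_config())
  .study_cache$report
}
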