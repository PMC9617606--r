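#' Noise simulation configuration
#'
#' The noise added to training inputs is made reconstruction-consistent by
#' backprojecting independent 2D Gaussian images over the acquisition tilt
#' range, mimicking how a tilt series' per-image noise propagates through
#' tomogram reconstruction.  Three projection filters mirror common
#' reconstruction modes: `none` (SIRT-like simple backprojection), `ramp`
#' (weighted backprojection) and `hamming` (Hamming-rolled ramp).
#'
#' @param filter_kind one of "none", "ramp", "hamming".
#' @param tilt_angles tilt angles in degrees (default -60..60 step 2).
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(filter_kind = c("none", "ramp", "hamming"),
                         tilt_angles = seq(-60, 60, by = 2)) {
  filter_kind <- match.arg(filter_kind)
  stopifnot(length(tilt_angles) >= 1,
            all(tilt_angles > -90 & tilt_angles < 90))
  structure(list(filter_kind = filter_kind, tilt_angles = tilt_angles),
            class = "noise_config")
}

# 1D reconstruction filter along the tilt-perpendicular axis, FFT order.
projection_filter <- function(n, kind) {
  k <- abs(fft_freqs(n)) / n          # cycles/pixel, 0..0.5
  switch(kind,
         none = rep(1, n),
         ramp = k / max(k),
         hamming = (k / max(k)) * (0.54 + 0.46 * cos(2 * pi * k)))
}

#' Simulate a reconstruction-consistent 3D noise volume
#'
#' For each tilt angle an independent iid Gaussian 2D image (x, y) is drawn,
#' optionally filtered along x, then smeared along the (tilted) beam
#' direction through the volume and accumulated; the beam tilts about the Y
#' axis, matching the tomographic geometry.  The result is normalized to
#' zero mean, unit standard deviation.  Its Fourier power lies almost
#' entirely inside the sampled tilt fan — like real reconstruction noise, it
#' has no power in the missing wedge.
#'
#' @param shape cube side in voxels (or length-3 dims of a cube).
#' @param cfg a [noise_config].
#' @param rng_seed integer seed.
#' @return 3D array with mean 0 and sd 1.
#' @export
backproject_noise <- function(shape, cfg = noise_config(), rng_seed = NULL) {
  if (length(shape) == 1) shape <- rep(shape, 3)
  stopifnot(length(unique(shape)) == 1)
  n <- shape[1]
  if (!length(cfg$tilt_angles)) stop("empty tilt angle list")
  filt <- projection_filter(n, cfg$filter_kind)
  # coordinate grids in the (x, z) plane, centred
  cx <- (n + 1) / 2
  xs <- seq_len(n) - cx
  zs <- seq_len(n) - cx
  vol <- array(0, dim = shape)
  with_seed(rng_seed, {
    for (theta in cfg$tilt_angles) {
      img <- matrix(stats::rnorm(n * n), n, n)   # (x, y)
      if (cfg$filter_kind != "none") {
        # filter each row spectrum along x
        img <- Re(stats::mvfft(stats::mvfft(img) * filt, inverse = TRUE)) / n
      }
      th <- theta * pi / 180
      # projection coordinate of voxel (x, z) on the tilted detector axis
      u <- outer(xs, zs, function(x, z) x * cos(th) + z * sin(th)) + cx
      f <- floor(u)
      wgt <- u - f
      ok0 <- f >= 1 & f <= n
      ok1 <- f + 1 >= 1 & f + 1 <= n
      i0 <- pmin(pmax(f, 1), n)
      i1 <- pmin(pmax(f + 1, 1), n)
      for (y in seq_len(n)) {
        col <- img[, y]
        plane <- (1 - wgt) * col[i0] * ok0 + wgt * col[i1] * ok1
        vol[, y, ] <- vol[, y, ] + plane
      }
    }
  })
  (vol - mean(vol)) / stats::sd(vol)
}

#' Add scaled noise to a training input
#'
#' The denoise level L is the ratio of the standard deviation of the added
#' noise to that of the subtomogram; the noise volume is rescaled so this
#' ratio holds exactly.  Targets are never altered.
#'
#' @param input_cube 3D array (non-constant).
#' @param noise 3D array of the same shape.
#' @param level denoise level L >= 0.
#' @return `input_cube + noise * L * sd(input_cube)/sd(noise)`.
#' @export
add_noise <- function(input_cube, noise, level) {
  stopifnot(identical(dim(as_volume(input_cube)), dim(as_volume(noise))),
            level >= 0)
  if (level == 0) return(input_cube)
  s_in <- stats::sd(as_volume(input_cube))
  if (s_in == 0) stop("zero-variance input cube")
  input_cube + as_volume(noise) * (level * s_in / stats::sd(as_volume(noise)))
}

#' Step-wise denoise schedule
#'
#' The first `warmup_iters` refinement iterations run without noise; the
#' level then increases by `step` every `step_every` iterations up to
#' `max_level`.  With the defaults (10 warmup, step 0.05 every 5, cap 0.2)
#' iterations 11-15 use 0.05 and iteration 30 reaches the final level 0.2.
#'
#' @param iteration 1-based refinement iteration.
#' @param warmup_iters noise-free iterations (default 10).
#' @param step level increment (default 0.05).
#' @param step_every iterations per increment (default 5).
#' @param max_level cap (default 0.2).
#' @return The denoise level for this iteration.
#' @export
denoise_schedule <- function(iteration, warmup_iters = 10, step = 0.05,
                             step_every = 5, max_level = 0.2) {
  stopifnot(iteration >= 1)
  if (iteration <= warmup_iters) return(0)
  min(max_level, step * ceiling((iteration - warmup_iters) / step_every))
}
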