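#' Deconvolution parameters
#'
#' Parameters of the Wiener-filter CTF deconvolution.  The spectral
#' signal-to-noise ratio is modelled empirically as
#' \deqn{SSNR(f) = e^{-f \cdot 100 F} \cdot 10^{S} \cdot H(f)}
#' where `f` is spatial frequency in cycles/pixel, `F` the fall-off, `S` the
#' strength, and `H` a cosine-ramp high-pass that is 0 at DC and reaches 1 at
#' `highpass_freq`.
#'
#' @param snrfalloff fall-off `F` (dimensionless, >= 0); larger values decay
#'   the assumed SSNR faster with frequency, damping high frequencies.
#' @param strength strength `S`; the SSNR plateau is `10^S`.
#' @param highpass_freq high-pass corner in cycles/pixel.
#' @param defocus defocus in micrometres, underfocus positive.
#' @param voltage acceleration voltage in kV.
#' @param cs spherical aberration in mm.
#' @param amplitude_contrast amplitude contrast fraction in [0, 1].
#' @param pixel_size pixel size in Angstrom.
#' @return A list of class `deconv_params`.
#' @export
deconv_params <- function(snrfalloff = 1, strength = 1, highpass_freq = 0.02,
                          defocus = 1, voltage = 300, cs = 2.7,
                          amplitude_contrast = 0.07, pixel_size = 10) {
  stopifnot(snrfalloff >= 0, highpass_freq > 0, voltage > 0, pixel_size > 0,
            amplitude_contrast >= 0, amplitude_contrast <= 1)
  structure(list(snrfalloff = snrfalloff, strength = strength,
                 highpass_freq = highpass_freq, defocus = defocus,
                 voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size),
            class = "deconv_params")
}

#' Empirical spectral signal-to-noise ratio
#'
#' @param f spatial frequency in cycles/pixel (vectorised, >= 0).
#' @param params a [deconv_params] object.
#' @return SSNR values (>= 0).
#' @export
ssnr <- function(f, params) {
  if (any(f < 0)) stop("spatial frequency must be non-negative")
  H <- 0.5 * (1 - cos(pi * pmin(f / params$highpass_freq, 1)))
  exp(-f * 100 * params$snrfalloff) * 10^params$strength * H
}

# Relativistic electron wavelength in Angstrom for voltage in kV.
electron_wavelength <- function(voltage_kv) {
  V <- voltage_kv * 1e3
  12.2639 / sqrt(V + 0.97845e-6 * V^2)
}

#' One-dimensional contrast transfer function
#'
#' Standard single-defocus CTF with phase shift
#' \eqn{\chi(f) = \pi \lambda \Delta z f^2 - (\pi/2) C_s \lambda^3 f^4}
#' (f in 1/Angstrom) and sign convention such that underfocus gives negative
#' contrast at low frequency: `CTF = -(sqrt(1-A^2) sin(chi) + A cos(chi))`.
#'
#' @param f spatial frequency in cycles/pixel (vectorised).
#' @param params a [deconv_params] object.
#' @return CTF values in [-1, 1].
#' @export
ctf_1d <- function(f, params) {
  if (any(f < 0)) stop("spatial frequency must be non-negative")
  fA <- f / params$pixel_size                # 1/Angstrom
  lambda <- electron_wavelength(params$voltage)
  dz <- params$defocus * 1e4                 # um -> Angstrom
  cs <- params$cs * 1e7                      # mm -> Angstrom
  chi <- pi * lambda * dz * fA^2 - (pi / 2) * cs * lambda^3 * fA^4
  A <- params$amplitude_contrast
  -(sqrt(1 - A^2) * sin(chi) + A * cos(chi))
}

# Wiener gain W(f) = CTF / (CTF^2 + 1/SSNR); 0 where SSNR is 0.
wiener_gain <- function(f, params) {
  s <- ssnr(f, params)
  ctf <- ctf_1d(f, params)
  w <- numeric(length(f))
  pos <- s > 0
  w[pos] <- ctf[pos] / (ctf[pos]^2 + 1 / s[pos])
  w
}

#' Wiener-filter CTF deconvolution
#'
#' Applies the radially symmetric Wiener filter
#' `W(f) = CTF(f) / (CTF(f)^2 + 1/SSNR(f))` in 3D Fourier space.  A single
#' defocus is assumed for the whole (already reconstructed) tomogram.  The DC
#' coefficient is left unchanged so the volume mean is preserved.
#'
#' @param vol a [tomogram] or 3D array (pixel size then taken from `params`).
#' @param params a [deconv_params] object.
#' @return Deconvolved volume of the same class and shape as `vol`.
#' @export
deconvolve <- function(vol, params) {
  data <- as_volume(vol)
  d <- dim(data)
  probe <- seq(0.001, 0.5, length.out = 64)
  if (all(ssnr(probe, params) == 0))
    stop("degenerate parameters: SSNR is identically zero")
  k1 <- fft_freqs(d[1]) / d[1]
  k2 <- fft_freqs(d[2]) / d[2]
  k3 <- fft_freqs(d[3]) / d[3]
  r <- sqrt(outer(outer(k1^2, k2^2, `+`), k3^2, `+`))
  W <- array(wiener_gain(as.vector(r), params), dim = d)
  W[1, 1, 1] <- 1   # DC untouched
  out <- Re(stats::fft(stats::fft(data) * W, inverse = TRUE)) / prod(d)
  with_data(vol, out)
}

#' Mask generation parameters
#'
#' @param density_percentage percentage of voxels kept by the density mask,
#'   in (0, 100].
#' @param std_percentage percentage kept by the local standard-deviation
#'   mask, in (0, 100].
#' @param gaussian_sigma Gaussian presmoothing sigma in voxels.
#' @param max_window side of the sliding maximum-filter cube (odd).
#' @param std_window side of the local standard-deviation cube (odd).
#' @param z_crop fraction in [0, 0.5) of Z slices zeroed at each of the top
#'   and bottom of the tomogram.
#' @return A list of class `mask_params`.
#' @export
mask_params <- function(density_percentage = 50, std_percentage = 50,
                        gaussian_sigma = 2, max_window = 5, std_window = 5,
                        z_crop = 0) {
  stopifnot(density_percentage > 0, density_percentage <= 100,
            std_percentage > 0, std_percentage <= 100,
            gaussian_sigma >= 0,
            max_window >= 1, max_window %% 2 == 1,
            std_window >= 1, std_window %% 2 == 1,
            z_crop >= 0, z_crop < 0.5)
  structure(list(density_percentage = density_percentage,
                 std_percentage = std_percentage,
                 gaussian_sigma = gaussian_sigma, max_window = max_window,
                 std_window = std_window, z_crop = z_crop),
            class = "mask_params")
}

# FFT-domain Gaussian smoothing (periodic boundaries).
gaussian_smooth <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  g <- function(n) exp(-2 * (pi * sigma * fft_freqs(n) / n)^2)
  G <- outer(outer(g(d[1]), g(d[2]), `*`), g(d[3]), `*`)
  Re(stats::fft(stats::fft(vol) * G, inverse = TRUE)) / prod(d)
}

# Keep the top `percentage`% of voxels of a score volume (strictly above the
# percentile threshold, so ties at the threshold are dropped).
threshold_top <- function(score, percentage) {
  if (percentage >= 100) return(array(TRUE, dim(score)))
  thr <- stats::quantile(score, probs = 1 - percentage / 100, names = FALSE)
  m <- score > thr
  if (!any(m)) warning("mask is empty: no voxel exceeds the threshold")
  m
}

#' Density mask
#'
#' Detects non-empty regions by intensity: the contrast-inverted volume
#' (density white) is Gaussian-smoothed, passed through a sliding cubic
#' maximum filter, and the brightest `density_percentage` percent of voxels
#' are kept.
#'
#' @param vol a [tomogram] or 3D array; densities are assumed dark (negative
#'   contrast), as in cryo-ET reconstructions.
#' @param p a [mask_params] object.
#' @return A logical 3D array, TRUE = keep.
#' @export
density_mask <- function(vol, p = mask_params()) {
  data <- -as_volume(vol)   # contrast inversion: density becomes bright
  sm <- gaussian_smooth(data, p$gaussian_sigma)
  mx <- max_filter3(sm, as.integer(p$max_window))
  threshold_top(mx, p$density_percentage)
}

#' Local standard-deviation mask
#'
#' Keeps the `std_percentage` percent of voxels with the highest standard
#' deviation over a small cube centred at each voxel, excluding featureless
#' regions.
#'
#' @inheritParams density_mask
#' @return A logical 3D array, TRUE = keep.
#' @export
std_mask <- function(vol, p = mask_params()) {
  data <- as_volume(vol)
  sd3 <- local_sd3(data, as.integer(p$std_window))
  threshold_top(sd3, p$std_percentage)
}

#' Combined sampling mask
#'
#' Intersection of [density_mask] and [std_mask], with the top and bottom
#' `z_crop` fraction of Z slices forced to FALSE (tomogram tops and bottoms
#' are usually vacuum or ice).
#'
#' @inheritParams density_mask
#' @return A logical 3D array, TRUE = voxels eligible for seed sampling.
#' @export
make_mask <- function(vol, p = mask_params()) {
  m <- density_mask(vol, p) & std_mask(vol, p)
  if (p$z_crop > 0) {
    nz <- dim(m)[3]
    ncrop <- floor(nz * p$z_crop)
    if (ncrop > 0) {
      m[, , seq_len(ncrop)] <- FALSE
      m[, , nz - seq_len(ncrop) + 1] <- FALSE
    }
  }
  m
}
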