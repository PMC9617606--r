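#' Missing-wedge specification
#'
#' Describes the tilt range of a single-axis tomographic acquisition with the
#' tilt axis along Y.  Fourier directions in the (kx, kz) plane whose angle
#' from the kx axis falls outside `[tilt_min, tilt_max]` were never sampled;
#' they form the missing wedge.
#'
#' @param tilt_min,tilt_max tilt range in degrees, `-90 < tilt_min <
#'   tilt_max < 90`.  Default is the common -60..+60 acquisition.
#' @return A list of class `wedge_spec`.
#' @export
wedge_spec <- function(tilt_min = -60, tilt_max = 60) {
  stopifnot(tilt_min > -90, tilt_max < 90, tilt_min < tilt_max)
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max, tilt_axis = "Y"),
            class = "wedge_spec")
}

#' Binary missing-wedge filter
#'
#' Builds the Fourier-space weight volume that is 0 inside the missing-wedge
#' region and 1 elsewhere.  A voxel with integer frequencies (kx, ky, kz) is
#' sampled iff the direction angle `atan2(kz, kx)`, folded to (-90, 90]
#' degrees, lies in `[tilt_min, tilt_max]` (boundary included); `ky` is
#' unconstrained and the DC voxel is always sampled.  The filter is laid out
#' in unshifted FFT order, ready to multiply `fft(vol)` elementwise, and is
#' Hermitian-symmetric so filtered real volumes stay real.
#'
#' @param shape integer length-3 volume dimensions.
#' @param w a [wedge_spec].
#' @return 3D numeric array of 0/1 weights in FFT order.
#' @export
wedge_filter <- function(shape, w = wedge_spec()) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  kx <- fft_freqs(shape[1])
  kz <- fft_freqs(shape[3])
  ang <- outer(kx, kz, function(x, z) atan2(z, x) * 180 / pi)
  # fold antipodal directions into (-90, 90]
  ang[ang > 90] <- ang[ang > 90] - 180
  ang[ang <= -90] <- ang[ang <= -90] + 180
  sampled <- (ang >= w$tilt_min & ang <= w$tilt_max)
  sampled[1, 1] <- TRUE  # DC
  # expand the (kx, kz) plane over the unconstrained ky axis
  aperm(array(as.numeric(sampled), dim = c(shape[1], shape[3], shape[2])),
        c(1, 3, 2))
}

# Is the Fourier direction (kx, ky, kz) inside the sampled tilt fan?
wedge_sampled <- function(kx, kz, w) {
  ang <- atan2(kz, kx) * 180 / pi
  ang[ang > 90] <- ang[ang > 90] - 180
  ang[ang <= -90] <- ang[ang <= -90] + 180
  (ang >= w$tilt_min & ang <= w$tilt_max) | (kx == 0 & kz == 0)
}

#' Inverse missing-wedge filter
#'
#' Complement of [wedge_filter]: 1 inside the missing wedge, 0 elsewhere,
#' with the DC voxel set to 0 (the mean is measured data and must come from
#' the original volume).
#'
#' @inheritParams wedge_filter
#' @return 3D numeric array of 0/1 weights in FFT order.
#' @export
inverse_wedge_filter <- function(shape, w = wedge_spec()) {
  f <- 1 - wedge_filter(shape, w)
  f[1, 1, 1] <- 0
  f
}

#' Apply a Fourier-space filter to a real volume
#'
#' Multiplies the volume's DFT by the filter and transforms back; the result
#' is real for any Hermitian-symmetric filter.  Binary filters are
#' idempotent.
#'
#' @param vol a [tomogram] or 3D array.
#' @param filt filter array of the same shape, in FFT order.
#' @return Filtered volume, same class and shape as `vol`.
#' @export
apply_fourier_filter <- function(vol, filt) {
  data <- as_volume(vol)
  if (!identical(dim(data), dim(filt))) stop("filter/volume shape mismatch")
  out <- Re(stats::fft(stats::fft(data) * filt, inverse = TRUE)) / length(data)
  with_data(vol, out)
}

#' The 24 proper rotations of a cube
#'
#' Enumerates the orientation-preserving symmetry group of the cube as signed
#' permutation matrices (determinant +1): each of the 6 faces can be turned
#' towards +Z, followed by 4 in-plane rotations.
#'
#' @return A list of 24 elements, each `list(matrix = <3x3>, label = <chr>)`.
#' @export
cube_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  rots <- list()
  for (p in perms) {
    for (sgn in 0:7) {
      s <- c(ifelse(bitwAnd(sgn, 1L) > 0, -1, 1),
             ifelse(bitwAnd(sgn, 2L) > 0, -1, 1),
             ifelse(bitwAnd(sgn, 4L) > 0, -1, 1))
      m <- matrix(0, 3, 3)
      for (i in 1:3) m[i, p[i]] <- s[i]
      if (abs(det(m) - 1) < 1e-9) {
        lab <- paste0("(", paste0(ifelse(s > 0, "+", "-"),
                                  c("x", "y", "z")[p], collapse = ","), ")")
        rots[[length(rots) + 1]] <- list(matrix = m, label = lab)
      }
    }
  }
  stopifnot(length(rots) == 24)
  rots
}

#' Rotations usable for training-pair generation
#'
#' Of the 24 cube rotations, those that map the missing-wedge region of
#' Fourier space onto itself produce an input identical in wedge direction to
#' the original and teach the network nothing; they are excluded.  For the
#' symmetric Y-axis wedge the excluded set is the identity and the three
#' 180-degree axis rotations, leaving 20 rotations.  The exclusion is
#' computed by comparing the wedge filter with its rotated copy, so
#' asymmetric tilt ranges are handled too.
#'
#' @param w a [wedge_spec].
#' @param probe_size half-width of the centred Fourier grid used for the
#'   preservation test.
#' @return List of rotations in the [cube_rotations] format.
#' @export
training_rotations <- function(w = wedge_spec(), probe_size = 8) {
  g <- seq(-probe_size, probe_size)
  kx <- rep(g, times = length(g)^2)
  ky <- rep(rep(g, each = length(g)), times = length(g))
  kz <- rep(g, each = length(g)^2)
  base <- wedge_sampled(kx, kz, w)
  Filter(function(r) {
    # wedge of the rotated volume at k equals original wedge at R^-1 k
    ri <- t(r$matrix)
    rx <- ri[1, 1] * kx + ri[1, 2] * ky + ri[1, 3] * kz
    rz <- ri[3, 1] * kx + ri[3, 2] * ky + ri[3, 3] * kz
    !all(wedge_sampled(rx, rz, w) == base)
  }, cube_rotations())
}

# Decompose a signed permutation matrix: row i has entry s[i] at column p[i],
# meaning output axis i takes input axis p[i] (reversed when s[i] == -1).
signed_perm <- function(m) {
  p <- apply(abs(m) > 0.5, 1, which)
  s <- m[cbind(1:3, p)]
  list(p = as.integer(p), s = as.integer(s))
}

#' Rotate a volume by a cubic-group rotation (lossless)
#'
#' Applies a signed axis permutation: no interpolation, every voxel value is
#' preserved, and `rotate_volume(rotate_volume(v, r), inverse)` restores the
#' input bit-exactly.  The rotation is about the volume centre in the
#' same centred-coordinate convention as the Fourier grid, so rotating a
#' wedge filter rotates its support consistently.
#'
#' @param vol a [tomogram] or 3D array (cubic unless the rotation maps each
#'   axis to one of equal length).
#' @param r a rotation from [cube_rotations], or a bare 3x3 signed
#'   permutation matrix.
#' @return Rotated volume, same class as `vol`.
#' @export
rotate_volume <- function(vol, r) {
  data <- as_volume(vol)
  m <- if (is.list(r)) r$matrix else r
  sp <- signed_perm(m)
  d <- dim(data)
  if (any(d[sp$p] != d)) stop("rotation permutes axes of unequal length")
  # output axis i indexes input axis p[i]; fetch with per-axis index vectors
  # on the input, then permute input axes into output order
  idx <- vector("list", 3)
  for (i in 1:3) {
    j <- sp$p[i]
    idx[[j]] <- if (sp$s[i] > 0) seq_len(d[j]) else rev(seq_len(d[j]))
  }
  tmp <- data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  # tmp axis j carries the output coordinate i with p[i] = j; aperm (whose
  # result axis k is argument axis perm[k]) brings the axes into output order
  out <- aperm(tmp, perm = sp$p)
  with_data(vol, out)
}

#' Merge restored missing-wedge information into the original volume
#'
#' Takes the predicted volume's Fourier content inside the missing wedge and
#' adds it to the original: `out = original + invFFT(inverse_wedge *
#' FFT(predicted))`.  The sampled region of the output is therefore exactly
#' the original's — measured information is never modified.
#'
#' @param original a [tomogram] or 3D array.
#' @param predicted volume of the same shape (e.g. a network prediction).
#' @param w a [wedge_spec].
#' @return Merged volume, same class as `original`.
#' @export
fourier_merge <- function(original, predicted, w = wedge_spec()) {
  a <- as_volume(original)
  b <- as_volume(predicted)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  inv <- inverse_wedge_filter(dim(a), w)
  wedge_part <- Re(stats::fft(stats::fft(b) * inv, inverse = TRUE)) / length(b)
  with_data(original, a + wedge_part)
}
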