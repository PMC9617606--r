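#' Generate a procedural ground-truth phantom
#'
#' Deterministic, band-limited test volumes with anisotropic features so
#' that missing-wedge loss (and its recovery) is visible: `sphere-shell`
#' (hollow shell, caps vanish under the wedge), `tube` (cylinders at random
#' orientations), `gaussian-assembly` (random blobs) and `lattice` (a grid
#' of spheres).  Volumes are low-pass filtered to `band_limit` of Nyquist
#' with a raised-cosine edge and normalized to zero mean, unit sd.
#'
#' @param shape cube side in voxels (or length-3 cube dims).
#' @param kind one of "sphere-shell", "tube", "gaussian-assembly",
#'   "lattice".
#' @param band_limit fraction of Nyquist retained (0, 1].
#' @param rng_seed integer seed; same seed, same phantom.
#' @param radius shell/lattice-sphere radius in voxels (default `side/4`).
#' @return A list of class `phantom`: `volume`, `kind`, `rng_seed`.
#' @export
make_phantom <- function(shape = 64,
                         kind = c("sphere-shell", "tube",
                                  "gaussian-assembly", "lattice"),
                         band_limit = 0.6, rng_seed = 1, radius = NULL) {
  kind <- match.arg(kind)
  if (length(shape) == 1) shape <- rep(shape, 3)
  stopifnot(length(unique(shape)) == 1, band_limit > 0, band_limit <= 1)
  n <- shape[1]
  if (is.null(radius)) radius <- n / 4
  c0 <- (n + 1) / 2
  ax <- seq_len(n) - c0
  X <- array(rep(ax, times = n * n), dim = shape)
  Y <- array(rep(rep(ax, each = n), times = n), dim = shape)
  Z <- array(rep(ax, each = n * n), dim = shape)
  vol <- with_seed(rng_seed, switch(kind,
    "sphere-shell" = {
      r <- sqrt(X^2 + Y^2 + Z^2)
      exp(-(r - radius)^2 / (2 * (n / 32)^2))
    },
    "tube" = {
      v <- array(0, shape)
      for (i in 1:3) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        p0 <- stats::runif(3, -n / 6, n / 6)
        dx <- X - p0[1]; dy <- Y - p0[2]; dz <- Z - p0[3]
        t <- dx * u[1] + dy * u[2] + dz * u[3]
        d2 <- (dx - t * u[1])^2 + (dy - t * u[2])^2 + (dz - t * u[3])^2
        v <- v + exp(-d2 / (2 * (n / 16)^2)) * (abs(t) < 0.4 * n)
      }
      v
    },
    "gaussian-assembly" = {
      v <- array(0, shape)
      for (i in 1:12) {
        p0 <- stats::runif(3, -0.3 * n, 0.3 * n)
        s <- stats::runif(1, n / 24, n / 10)
        v <- v + exp(-((X - p0[1])^2 + (Y - p0[2])^2 + (Z - p0[3])^2) /
                       (2 * s^2))
      }
      v
    },
    "lattice" = {
      sp <- max(4, round(n / 4))
      cen <- as.matrix(expand.grid(x = c(-sp, 0, sp), y = c(-sp, 0, sp),
                                   z = c(-sp, 0, sp)))
      v <- array(0, shape)
      for (i in seq_len(nrow(cen)))
        v <- v + exp(-((X - cen[i, 1])^2 + (Y - cen[i, 2])^2 +
                         (Z - cen[i, 3])^2) / (2 * (n / 24)^2))
      v
    }))
  vol <- lowpass(vol, band_limit)
  vol <- (vol - mean(vol)) / stats::sd(vol)
  structure(list(volume = vol, kind = kind, rng_seed = rng_seed,
                 band_limit = band_limit),
            class = "phantom")
}

# Raised-cosine low-pass: unity below 0.85*fc, zero at fc (fc as a fraction
# of Nyquist), so virtually no power survives beyond the stated band limit.
lowpass <- function(vol, band_limit) {
  d <- dim(vol)
  k1 <- fft_freqs(d[1]) / d[1]
  k2 <- fft_freqs(d[2]) / d[2]
  k3 <- fft_freqs(d[3]) / d[3]
  r <- sqrt(outer(outer(k1^2, k2^2, `+`), k3^2, `+`)) / 0.5  # fraction of Nyquist
  lo <- 0.85 * band_limit
  w <- array(0, d)
  w[r <= lo] <- 1
  ramp <- r > lo & r < band_limit
  w[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - lo) / (band_limit - lo)))
  Re(stats::fft(stats::fft(vol) * w, inverse = TRUE)) / length(vol)
}

# Uniform random rotation matrix via quaternions.
random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Rotate a volume by an arbitrary rotation (trilinear interpolation)
#'
#' The only interpolating rotation in the package; used to pose phantoms in
#' random orientations.  Values outside the volume are mirror-reflected.
#'
#' @param vol 3D array or [tomogram].
#' @param R 3x3 rotation matrix.
#' @return Rotated volume.
#' @export
rotate_volume_trilinear <- function(vol, R) {
  data <- as_volume(vol)
  out <- rotate_trilinear(data, t(R))   # out(y) = in(R^-1 y), R^-1 = t(R)
  with_data(vol, out)
}

#' Simulate the wedge-corruption benchmark
#'
#' Rotates a phantom into `n_orientations` random orientations and imposes
#' the missing wedge on each in Fourier space, producing corrupted cubes
#' with the standard Z-elongation artefacts plus the matching ground-truth
#' rotated copies for scoring.
#'
#' @param phantom a [make_phantom] result (or bare cubic array).
#' @param n_orientations number of random orientations (>= 1).
#' @param w a [wedge_spec].
#' @param rng_seed integer seed for the orientations.
#' @return List with `corrupted` (a `subtomo_set`) and `truth` (list of
#'   ground-truth rotated cubes) plus `rotations`.
#' @export
simulate_benchmark <- function(phantom, n_orientations = 10,
                               w = wedge_spec(), rng_seed = 1) {
  vol <- if (inherits(phantom, "phantom")) phantom$volume else as_volume(phantom)
  stopifnot(n_orientations >= 1)
  filt <- wedge_filter(dim(vol), w)
  rots <- with_seed(rng_seed,
                    lapply(seq_len(n_orientations),
                           function(i) random_rotation_matrix()))
  truth <- lapply(rots, function(R) rotate_volume_trilinear(vol, R))
  corrupted <- lapply(truth, function(v) apply_fourier_filter(v, filt))
  list(corrupted = subtomo_set(corrupted), truth = truth, rotations = rots)
}

#' Score missing-wedge recovery against ground truth
#'
#' Pearson correlation in real space, plus normalized Fourier-space
#' cross-correlations restricted to the missing-wedge region and to the
#' sampled (non-wedge) region.  A perfectly corrected volume scores (1,1,1);
#' a merely wedge-filtered one scores about (high, 0, 1).
#'
#' @param corrected candidate volume.
#' @param truth ground-truth volume, same shape.
#' @param w a [wedge_spec].
#' @return Named numeric: `real_r`, `wedge_r`, `nonwedge_r`.
#' @export
recovery_score <- function(corrected, truth, w = wedge_spec()) {
  a <- as_volume(corrected); b <- as_volume(truth)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("constant input")
  fa <- stats::fft(a); fb <- stats::fft(b)
  wedge <- inverse_wedge_filter(dim(a), w) > 0
  sampled <- !wedge
  sampled[1, 1, 1] <- FALSE   # DC carries the mean, not structure
  spec_r <- function(sel) {
    num <- sum(Re(fa[sel] * Conj(fb[sel])))
    num / sqrt(sum(Mod(fa[sel])^2) * sum(Mod(fb[sel])^2))
  }
  c(real_r = stats::cor(as.vector(a), as.vector(b)),
    wedge_r = spec_r(wedge),
    nonwedge_r = spec_r(sampled))
}
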