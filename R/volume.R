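#' Construct a tomogram object
#'
#' A tomogram is a 3D grid of voxel intensities together with its pixel size
#' in Angstrom per voxel.  Volumes are stored as base-R numeric arrays with
#' `dim = c(nx, ny, nz)`: the first (fastest-varying) index is X, matching the
#' on-disk layout of MRC files, and indices are 1-based as usual in R.
#'
#' @param data 3D numeric array of voxel intensities.
#' @param pixel_size voxel size in Angstrom (> 0).
#' @param origin numeric length-3 voxel offset (default `c(0, 0, 0)`).
#' @param name source identifier, e.g. the file the volume came from.
#' @return An object of class `tomogram`: a list with elements `data`,
#'   `pixel_size`, `origin` and `name`.
#' @export
tomogram <- function(data, pixel_size = 1, origin = c(0, 0, 0), name = "") {
  data <- as_volume(data)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || !is.finite(pixel_size) ||
      pixel_size <= 0)
    stop("pixel_size must be a single positive number (Angstrom/voxel)")
  if (any(!is.finite(data)))
    stop("tomogram data must be finite (no NA/NaN/Inf)")
  structure(list(data = data, pixel_size = pixel_size,
                 origin = as.numeric(origin), name = as.character(name)),
            class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("tomogram '%s': %d x %d x %d voxels, %.4g A/voxel\n",
              x$name, d[1], d[2], d[3], x$pixel_size))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @export
dim.tomogram <- function(x) dim(x$data)

# Coerce tomogram or array input to a plain 3D numeric array.
as_volume <- function(x) {
  if (inherits(x, "tomogram")) x <- x$data
  if (is.null(dim(x)) || length(dim(x)) != 3)
    stop("expected a 3D volume (array with three dimensions)")
  if (!is.numeric(x)) stop("volume must be numeric")
  if (any(dim(x) < 1)) stop("all three dimensions must be >= 1")
  storage.mode(x) <- "double"
  x
}

# Replace the voxel data of a tomogram, keeping metadata.
with_data <- function(tomo, data) {
  if (inherits(tomo, "tomogram")) {
    tomo$data <- data
    tomo
  } else data
}

# Evaluate expr with a temporarily seeded RNG, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}

# Derive a reproducible child seed from a master seed (kept below 2^31).
derive_seed <- function(master, ...) {
  ids <- c(as.integer(master), as.integer(c(...)))
  s <- 0
  for (v in ids) s <- (s * 69069 + v + 12345) %% 2147483647
  as.integer(s)
}

# Centre-crop a cubic region of side `size` from a 3D array.
center_crop <- function(vol, size) {
  vol <- as_volume(vol)
  d <- dim(vol)
  if (any(size > d)) stop("crop size exceeds volume dimensions")
  s <- (d - size) %/% 2
  vol[s[1] + seq_len(size), s[2] + seq_len(size), s[3] + seq_len(size), drop = FALSE]
}

# Signed integer frequencies of an n-point DFT in unshifted (fft) order.
fft_freqs <- function(n) {
  k <- seq_len(n) - 1L
  k[k > n %/% 2] <- k[k > n %/% 2] - n
  k
}
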