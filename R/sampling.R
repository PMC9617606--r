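#' Sample seed coordinates for subtomogram extraction
#'
#' Draws `count` voxel coordinates uniformly from the eligible region: mask
#' voxels whose surrounding cube of side `cube_size` lies fully inside the
#' volume.  Seeds may repeat positions' neighbourhoods (no minimum spacing).
#'
#' @param mask logical 3D array (TRUE = eligible), e.g. from [make_mask];
#'   may also be `NULL` for "everywhere".
#' @param count number of seeds.
#' @param cube_size side of the cubes that will be extracted (voxels).
#' @param rng_seed integer seed for reproducibility.
#' @param shape required if `mask` is NULL: volume dimensions.
#' @return Integer matrix `count x 3` of 1-based (x, y, z) voxel coordinates.
#' @export
sample_seeds <- function(mask, count, cube_size, rng_seed = NULL,
                         shape = NULL) {
  if (is.null(mask)) {
    stopifnot(!is.null(shape))
    mask <- array(TRUE, shape)
  }
  d <- dim(mask)
  half_lo <- (cube_size - 1L) %/% 2L      # voxels before the seed
  half_hi <- cube_size %/% 2L             # voxels after the seed
  elig <- mask
  for (ax in 1:3) {
    ok <- seq_len(d[ax]) > half_lo & seq_len(d[ax]) + half_hi <= d[ax]
    idx <- slice.index(elig, ax)
    elig <- elig & array(ok[idx], dim = d)
  }
  pool <- which(elig)
  if (length(pool) < count)
    stop(sprintf("only %d eligible voxels for %d requested seeds",
                 length(pool), count))
  picks <- with_seed(rng_seed, sample(pool, count))
  arrayInd(picks, d)
}

#' Percentile normalization
#'
#' Linearly rescales a volume so the 5th percentile maps to 0 and the 95th to
#' 1; 90 percent of voxel values then lie strictly between zero and one.  The
#' affine transform is recorded in attributes `norm_offset`/`norm_scale` so
#' it can be inverted with [denormalize].
#'
#' @param vol a [tomogram] or 3D array, non-constant.
#' @param lower,upper percentile pair (defaults 0.05 and 0.95).
#' @return Normalized volume with the transform recorded as attributes.
#' @export
normalize_percentile <- function(vol, lower = 0.05, upper = 0.95) {
  data <- as_volume(vol)
  q <- stats::quantile(data, probs = c(lower, upper), names = FALSE)
  if (q[2] <= q[1]) stop("degenerate input: percentile range is empty")
  out <- (data - q[1]) / (q[2] - q[1])
  attr(out, "norm_offset") <- q[1]
  attr(out, "norm_scale") <- q[2] - q[1]
  with_data(vol, out)
}

#' Invert a recorded percentile normalization
#'
#' @param vol volume returned by [normalize_percentile] (or any volume, with
#'   `offset`/`scale` given explicitly).
#' @param offset,scale transform parameters; default to the recorded ones.
#' @return Volume on the original intensity scale.
#' @export
denormalize <- function(vol, offset = NULL, scale = NULL) {
  data <- as_volume(vol)
  if (is.null(offset)) offset <- attr(data, "norm_offset")
  if (is.null(scale)) scale <- attr(data, "norm_scale")
  if (is.null(offset) || is.null(scale))
    stop("no recorded normalization transform; pass offset and scale")
  out <- data * scale + offset
  attr(out, "norm_offset") <- NULL
  attr(out, "norm_scale") <- NULL
  with_data(vol, out)
}

#' Extract subtomograms
#'
#' Crops cubes of side `cube_size` centred at randomly sampled seeds,
#' inverts their contrast (cryo-ET density is dark; the network trains on
#' white density) and percentile-normalizes each cube.  Optionally assigns
#' cubes at random to two halves for gold-standard processing.
#'
#' @param tomo a [tomogram].
#' @param mask logical mask of eligible seed voxels, or NULL for everywhere.
#' @param count number of subtomograms.
#' @param cube_size cube side in voxels.
#' @param rng_seed integer seed.
#' @param split logical; randomly split cubes into two disjoint halves of
#'   sizes ceiling(n/2) and floor(n/2).
#' @return An object of class `subtomo_set`: list with `cubes` (list of 3D
#'   arrays), `seeds`, `half_id` (1/2 or NA), `norm` (per-cube offset/scale),
#'   `cube_size`, `pixel_size`, `source`.
#' @export
extract_subtomograms <- function(tomo, mask = NULL, count = 100,
                                 cube_size = 96, rng_seed = NULL,
                                 split = FALSE) {
  data <- as_volume(tomo)
  seeds <- sample_seeds(mask, count, cube_size,
                        rng_seed = if (is.null(rng_seed)) NULL
                                   else derive_seed(rng_seed, 1),
                        shape = dim(data))
  half_lo <- (cube_size - 1L) %/% 2L
  cubes <- vector("list", count)
  norm <- vector("list", count)
  for (i in seq_len(count)) {
    s <- seeds[i, ]
    cube <- data[s[1] - half_lo + seq_len(cube_size) - 1L,
                 s[2] - half_lo + seq_len(cube_size) - 1L,
                 s[3] - half_lo + seq_len(cube_size) - 1L, drop = FALSE]
    cube <- normalize_percentile(-cube)
    norm[[i]] <- c(offset = attr(cube, "norm_offset"),
                   scale = attr(cube, "norm_scale"))
    attr(cube, "norm_offset") <- NULL
    attr(cube, "norm_scale") <- NULL
    cubes[[i]] <- cube
  }
  half_id <- rep(NA_integer_, count)
  if (split) {
    perm <- with_seed(if (is.null(rng_seed)) NULL else derive_seed(rng_seed, 2),
                      sample.int(count))
    half_id[perm[seq_len(ceiling(count / 2))]] <- 1L
    half_id[is.na(half_id)] <- 2L
  }
  structure(list(cubes = cubes, seeds = seeds, half_id = half_id,
                 norm = norm, cube_size = cube_size,
                 pixel_size = if (inherits(tomo, "tomogram")) tomo$pixel_size else 1,
                 source = if (inherits(tomo, "tomogram")) tomo$name else ""),
            class = "subtomo_set")
}

#' Build a subtomogram set from existing cubes
#'
#' Wraps a list of equally sized cubic arrays (e.g. simulated volumes) in the
#' container used by the refinement loop.
#'
#' @param cubes list of cubic 3D arrays, all the same size.
#' @param pixel_size pixel size in Angstrom.
#' @return A `subtomo_set`.
#' @export
subtomo_set <- function(cubes, pixel_size = 1) {
  stopifnot(length(cubes) >= 1)
  sz <- dim(cubes[[1]])
  stopifnot(length(unique(sz)) == 1,
            all(vapply(cubes, function(c) identical(dim(c), sz), TRUE)))
  structure(list(cubes = lapply(cubes, as_volume), seeds = NULL,
                 half_id = rep(NA_integer_, length(cubes)),
                 norm = NULL, cube_size = sz[1], pixel_size = pixel_size,
                 source = ""),
            class = "subtomo_set")
}

#' @export
print.subtomo_set <- function(x, ...) {
  cat(sprintf("subtomo_set: %d cubes of %d^3 voxels (%.4g A/voxel)\n",
              length(x$cubes), x$cube_size, x$pixel_size))
  if (!all(is.na(x$half_id)))
    cat(sprintf("  halves: %d / %d\n", sum(x$half_id == 1, na.rm = TRUE),
                sum(x$half_id == 2, na.rm = TRUE)))
  invisible(x)
}

#' Build one training pair
#'
#' Rotates a cube by a cubic-group rotation, producing a volume whose
#' missing wedge points in a new direction; the network input additionally
#' receives the standard wedge filter, so it lacks information in two wedge
#' orientations while the target lacks it in one.  Both are centre-cropped
#' AFTER filtering so edge artefacts of the Fourier filter are trimmed away.
#'
#' @param cube cubic 3D array.
#' @param r rotation (from [training_rotations]).
#' @param w a [wedge_spec].
#' @param crop_size side of the final training volumes (<= cube side).
#' @return `list(input =, target =, rotation =)` of class `training_pair`.
#' @export
make_training_pair <- function(cube, r, w = wedge_spec(), crop_size) {
  cube <- as_volume(cube)
  if (crop_size > dim(cube)[1]) stop("crop_size exceeds cube size")
  rot <- rotate_volume(cube, r)
  filt <- wedge_filter(dim(rot), w)
  input_full <- apply_fourier_filter(rot, filt)
  structure(list(input = center_crop(input_full, crop_size),
                 target = center_crop(rot, crop_size),
                 rotation = r),
            class = "training_pair")
}

#' Build the per-iteration training dataset
#'
#' Forms all cube-by-rotation training pairs (20 rotations per cube) and
#' shuffles them deterministically.
#'
#' @param cubes a `subtomo_set`.
#' @param w a [wedge_spec].
#' @param crop_size training volume side.
#' @param rng_seed shuffle seed.
#' @param rotations optional rotation list (defaults to
#'   [training_rotations]).
#' @return List of `training_pair` objects (each also carries
#'   `source_index`).
#' @export
build_epoch_dataset <- function(cubes, w = wedge_spec(), crop_size,
                                rng_seed = NULL, rotations = NULL) {
  stopifnot(inherits(cubes, "subtomo_set"), length(cubes$cubes) >= 1)
  if (is.null(rotations)) rotations <- training_rotations(w)
  pairs <- vector("list", length(cubes$cubes) * length(rotations))
  k <- 1
  for (i in seq_along(cubes$cubes)) {
    for (r in rotations) {
      p <- make_training_pair(cubes$cubes[[i]], r, w, crop_size)
      p$source_index <- i
      pairs[[k]] <- p
      k <- k + 1
    }
  }
  ord <- with_seed(rng_seed, sample.int(length(pairs)))
  pairs[ord]
}
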