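#' Plan an overlap-tile decomposition
#'
#' Splits a volume into disjoint core regions that tile it exactly; each
#' core is predicted from a padded read window of side `crop_size` so that
#' every core voxel has at least `margin` voxels of context, which removes
#' seam artefacts at chunk borders.  Windows near the volume boundary read
#' from a reflect-padded copy.
#'
#' @param shape integer length-3 volume dimensions.
#' @param crop_size side of the network input window.
#' @param margin context voxels on every side of a core
#'   (`crop_size > 2 * margin`).
#' @return A list of class `tile_plan`: per tile, the core index ranges in
#'   the original volume and the read window in the padded volume.
#' @export
plan_tiles <- function(shape, crop_size, margin = crop_size %/% 4) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, crop_size > 2 * margin, margin >= 0)
  core <- crop_size - 2L * margin
  starts <- lapply(shape, function(n) seq(1L, n, by = core))
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  psize <- pmax(shape + 2L * margin, crop_size)  # reflect-padded volume size
  tiles <- lapply(seq_len(nrow(grid)), function(i) {
    s <- as.integer(grid[i, ])
    e <- pmin(s + core - 1L, shape)
    # read window in padded coordinates (original index o sits at o + margin);
    # clamp so the window always has side exactly crop_size
    rs <- pmax(pmin(s, psize - crop_size + 1L), 1L)
    list(core_start = s, core_end = e,
         read_start = rs, read_end = rs + crop_size - 1L,
         core_offset = s - rs + margin)  # core position inside the window
  })
  structure(list(tiles = tiles, crop_size = crop_size, margin = margin,
                 shape = shape),
            class = "tile_plan")
}

# Reflect-pad a volume by `m` voxels on every side (and grow it to at least
# `minsize` per axis if needed).
reflect_pad <- function(vol, m, minsize = 0) {
  d <- dim(vol)
  idx <- lapply(d, function(n) {
    i <- seq(1 - m, max(n + m, minsize - m))
    period <- max(2 * (n - 1), 1)
    i <- ((i - 1) %% period + period) %% period + 1
    i[i > n] <- period + 2 - i[i > n]
    i
  })
  vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Predict a full tomogram with the overlap-tile strategy
#'
#' The tomogram is contrast-inverted and percentile-normalized with a single
#' tomogram-level transform (so all tiles share one intensity frame),
#' predicted tile by tile, and the disjoint cores are montaged back; finally
#' the inverse transform restores the original intensity scale.  Output
#' voxels are each written exactly once.
#'
#' @param tomo a [tomogram] or 3D array.
#' @param model a `unet_model` or prediction function (see [predict_cube]).
#' @param crop_size network input window side.
#' @param margin overlap margin (default `crop_size / 4`).
#' @return Predicted volume, same class/shape/pixel size as the input.
#' @export
predict_full <- function(tomo, model, crop_size = 96,
                         margin = crop_size %/% 4) {
  data <- as_volume(tomo)
  plan <- plan_tiles(dim(data), crop_size, margin)
  norm <- normalize_percentile(-data)
  offset <- attr(norm, "norm_offset"); scale <- attr(norm, "norm_scale")
  padded <- reflect_pad(norm, plan$margin, minsize = crop_size)
  out <- array(NA_real_, dim(data))
  for (t in plan$tiles) {
    win <- padded[t$read_start[1]:t$read_end[1],
                  t$read_start[2]:t$read_end[2],
                  t$read_start[3]:t$read_end[3], drop = FALSE]
    pred <- predict_cube(model, win)
    len <- t$core_end - t$core_start + 1L
    o <- t$core_offset
    out[t$core_start[1]:t$core_end[1],
        t$core_start[2]:t$core_end[2],
        t$core_start[3]:t$core_end[3]] <-
      pred[o[1] + seq_len(len[1]), o[2] + seq_len(len[2]),
           o[3] + seq_len(len[3])]
  }
  stopifnot(!anyNA(out))
  out <- -(out * scale + offset)   # undo normalization, then contrast
  with_data(tomo, out)
}
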