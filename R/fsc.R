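#' Fourier shell correlation
#'
#' Per-shell normalized cross-correlation of the Fourier coefficients of two
#' volumes.  Shells are one Fourier voxel wide; shell s collects voxels with
#' `round(|k|) == s` on the integer frequency grid.
#'
#' @param a,b same-shape 3D arrays or [tomogram]s.
#' @param pixel_size Angstrom per voxel (taken from `a` if a tomogram).
#' @return An object of class `fsc_curve`: data.frame with columns `shell`,
#'   `freq` (cycles/pixel), `fsc`, `n_voxels`, plus attribute `pixel_size`.
#' @export
fsc <- function(a, b, pixel_size = NULL) {
  if (is.null(pixel_size))
    pixel_size <- if (inherits(a, "tomogram")) a$pixel_size else 1
  av <- as_volume(a); bv <- as_volume(b)
  if (!identical(dim(av), dim(bv))) stop("volumes must have the same shape")
  fa <- stats::fft(av); fb <- stats::fft(bv)
  sh <- shell_index(dim(av))
  fsc_from_masked(fa, fb, sh$shell, sh$nmax, dim(av)[1], pixel_size)
}

# shell number per Fourier voxel (round(|k|)), and the highest full shell
shell_index <- function(d) {
  k1 <- fft_freqs(d[1]); k2 <- fft_freqs(d[2]); k3 <- fft_freqs(d[3])
  r <- sqrt(outer(outer(k1^2, k2^2, `+`), k3^2, `+`))
  list(shell = as.integer(round(r)), nmax = min(d) %/% 2L)
}

fsc_from_masked <- function(fa, fb, shell, nmax, n, pixel_size,
                            keep = NULL) {
  num <- Re(fa * Conj(fb))
  pa <- Mod(fa)^2
  pb <- Mod(fb)^2
  if (!is.null(keep)) {
    sel <- keep & shell <= nmax
  } else sel <- shell <= nmax
  s <- shell[sel]
  sums_n <- rowsum(num[sel], s)
  sums_a <- rowsum(pa[sel], s)
  sums_b <- rowsum(pb[sel], s)
  counts <- rowsum(rep(1, length(s)), s)
  shells <- as.integer(rownames(sums_n))
  vals <- as.vector(sums_n) / sqrt(as.vector(sums_a) * as.vector(sums_b))
  df <- data.frame(shell = shells, freq = shells / n, fsc = vals,
                   n_voxels = as.vector(counts))
  # report shells 1..nmax (DC-only shell 0 dropped); missing shells are NA
  full <- data.frame(shell = seq_len(nmax))
  df <- merge(full, df, by = "shell", all.x = TRUE)
  df$freq <- df$shell / n
  attr(df, "pixel_size") <- pixel_size
  class(df) <- c("fsc_curve", "data.frame")
  df
}

#' Conical (directional) Fourier shell correlation
#'
#' FSC restricted to Fourier voxels lying within the double cone of
#' `half_angle` degrees about `direction`; measures resolution anisotropy
#' along that axis.  Shells with no voxels in the cone are reported NA.
#'
#' @inheritParams fsc
#' @param direction length-3 vector (need not be normalized), e.g.
#'   `c(0, 0, 1)` for the Z (beam) axis.
#' @param half_angle cone half-angle in degrees (default 20).
#' @return An `fsc_curve` restricted to the cone.
#' @export
conical_fsc <- function(a, b, direction, half_angle = 20,
                        pixel_size = NULL) {
  if (is.null(pixel_size))
    pixel_size <- if (inherits(a, "tomogram")) a$pixel_size else 1
  av <- as_volume(a); bv <- as_volume(b)
  if (!identical(dim(av), dim(bv))) stop("volumes must have the same shape")
  u <- direction / sqrt(sum(direction^2))
  d <- dim(av)
  k1 <- fft_freqs(d[1]); k2 <- fft_freqs(d[2]); k3 <- fft_freqs(d[3])
  dot <- outer(outer(k1 * u[1], k2 * u[2], `+`), k3 * u[3], `+`)
  r <- sqrt(outer(outer(k1^2, k2^2, `+`), k3^2, `+`))
  cosang <- array(0, d)
  nz <- r > 0
  cosang[nz] <- abs(dot[nz]) / r[nz]
  keep <- nz & cosang >= cos(half_angle * pi / 180)
  keep[1, 1, 1] <- TRUE
  sh <- shell_index(d)
  fsc_from_masked(stats::fft(av), stats::fft(bv), sh$shell, sh$nmax, d[1],
                  pixel_size, keep = keep)
}

#' Resolution at an FSC cutoff
#'
#' Finds the first downward crossing of the curve through `cutoff` by linear
#' interpolation and converts to Angstrom (`pixel_size / freq`).  A curve
#' that never drops below the cutoff reports the Nyquist resolution
#' (`2 * pixel_size`); a curve already below it at the first shell reports
#' the lowest-frequency shell with attribute `below_cutoff = TRUE`.
#'
#' @param curve an `fsc_curve`.
#' @param cutoff FSC threshold, conventionally 0.5 or 0.143.
#' @return Resolution in Angstrom.
#' @export
resolution_at <- function(curve, cutoff = 0.143) {
  stopifnot(inherits(curve, "fsc_curve"))
  px <- attr(curve, "pixel_size")
  ok <- !is.na(curve$fsc)
  f <- curve$freq[ok]; v <- curve$fsc[ok]
  if (length(v) < 2) stop("need at least two shells")
  if (v[1] < cutoff) {
    res <- px / f[1]
    attr(res, "below_cutoff") <- TRUE
    return(res)
  }
  below <- which(v < cutoff)
  if (!length(below)) return(2 * px)   # never crosses: Nyquist
  i <- below[1]
  f_star <- f[i - 1] + (cutoff - v[i - 1]) * (f[i] - f[i - 1]) /
    (v[i] - v[i - 1])
  px / f_star
}

#' Gold-standard 3D FSC between two half-reconstructions
#'
#' Crops `n_cubes` cubic volumes at matched positions from the two half
#' volumes (evenly placed along the largest axes), computes directional FSC
#' over a grid of cone axes for each cube, and averages the curves over
#' cubes.  Per-direction resolutions at the 0.5 and 0.143 cutoffs summarise
#' the anisotropy.
#'
#' @param half1,half2 same-shape volumes from independently processed halves.
#' @param n_cubes number of cubes (default 4).
#' @param cube cube side in voxels.
#' @param half_angle cone half-angle in degrees (default 20).
#' @param n_directions number of cone axes spread over the hemisphere
#'   (default 26: the unique axis directions of a 3x3x3 neighbourhood).
#' @param pixel_size Angstrom per voxel.
#' @return An object of class `fsc3d`: list with `directions` (matrix n x 3),
#'   `curves` (shells x directions matrix of averaged FSC), `freq`,
#'   `resolution_05`, `resolution_143` (per direction, Angstrom).
#' @export
gold_standard_3dfsc <- function(half1, half2, n_cubes = 4, cube = NULL,
                                half_angle = 20, n_directions = 26,
                                pixel_size = NULL) {
  if (is.null(pixel_size))
    pixel_size <- if (inherits(half1, "tomogram")) half1$pixel_size else 1
  a <- as_volume(half1); b <- as_volume(half2)
  if (!identical(dim(a), dim(b))) stop("half-volumes must have the same shape")
  d <- dim(a)
  if (is.null(cube)) cube <- min(d, 64L)
  if (any(cube > d)) stop("volumes too small for requested cube size")
  dirs <- hemisphere_directions(n_directions)
  positions <- matched_positions(d, cube, n_cubes)
  acc <- NULL
  for (p in seq_len(nrow(positions))) {
    s <- positions[p, ]
    ca <- a[s[1] + seq_len(cube) - 1, s[2] + seq_len(cube) - 1,
            s[3] + seq_len(cube) - 1, drop = FALSE]
    cb <- b[s[1] + seq_len(cube) - 1, s[2] + seq_len(cube) - 1,
            s[3] + seq_len(cube) - 1, drop = FALSE]
    mat <- vapply(seq_len(nrow(dirs)), function(j)
      conical_fsc(ca, cb, dirs[j, ], half_angle, pixel_size)$fsc,
      numeric(cube %/% 2))
    acc <- if (is.null(acc)) mat else acc + mat
  }
  curves <- acc / nrow(positions)
  freq <- seq_len(cube %/% 2) / cube
  mk_curve <- function(v) {
    df <- data.frame(shell = seq_along(v), freq = freq, fsc = v,
                     n_voxels = NA)
    attr(df, "pixel_size") <- pixel_size
    class(df) <- c("fsc_curve", "data.frame")
    df
  }
  structure(list(directions = dirs, curves = curves, freq = freq,
                 pixel_size = pixel_size,
                 resolution_05 = apply(curves, 2, function(v)
                   as.numeric(resolution_at(mk_curve(v), 0.5))),
                 resolution_143 = apply(curves, 2, function(v)
                   as.numeric(resolution_at(mk_curve(v), 0.143)))),
            class = "fsc3d")
}

# Even cube placement: diagonal positions through the volume.
matched_positions <- function(d, cube, n_cubes) {
  t(vapply(seq_len(n_cubes), function(i) {
    frac <- if (n_cubes == 1) 0.5 else (i - 1) / (n_cubes - 1)
    as.integer(pmax(1, pmin(d - cube + 1, round(1 + frac * (d - cube)))))
  }, integer(3)))
}

# Cone axis directions: unique (up to inversion) integer directions of a
# 3x3x3 neighbourhood, or a Fibonacci hemisphere for other counts.
hemisphere_directions <- function(n) {
  if (n == 26) {
    g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
    g <- g[!(g$x == 0 & g$y == 0 & g$z == 0), ]
    m <- as.matrix(g)
    keep <- apply(m, 1, function(v) {
      nzfirst <- v[which(v != 0)[1]]
      nzfirst > 0
    })
    m <- m[keep, , drop = FALSE]
    return(m / sqrt(rowSums(m^2)))
  }
  i <- seq_len(n)
  phi <- (1 + sqrt(5)) / 2
  z <- (i - 0.5) / n
  theta <- 2 * pi * i / phi
  cbind(sqrt(1 - z^2) * cos(theta), sqrt(1 - z^2) * sin(theta), z)
}

#' @export
print.fsc3d <- function(x, ...) {
  cat(sprintf("fsc3d: %d cone directions, %d shells, %.4g A/voxel\n",
              nrow(x$directions), length(x$freq), x$pixel_size))
  cat(sprintf("  resolution at 0.143: %.3g - %.3g A (best - worst)\n",
              min(x$resolution_143), max(x$resolution_143)))
  invisible(x)
}

#' Write an FSC curve as tab-separated text
#'
#' @param curve an `fsc_curve`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fsc <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
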