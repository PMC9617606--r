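# Shared fixture builders; everything is generated in code at test time.

rand_vol <- function(n, seed = 1) {
  set.seed(seed)
  array(rnorm(n^3), dim = rep(n, 3))
}

# Brute-force rotation oracle: loop over voxels, apply the matrix around the
# array centre.  Independent of rotate_volume's index gymnastics.
rotate_brute <- function(v, R) {
  n <- dim(v)[1]
  c0 <- (n + 1) / 2
  out <- array(NA_real_, dim(v))
  for (z in 1:n) for (y in 1:n) for (x in 1:n) {
    xx <- as.vector(t(R) %*% (c(x, y, z) - c0)) + c0
    out[x, y, z] <- v[xx[1], xx[2], xx[3]]
  }
  out
}

# Radial average of a volume's Fourier power spectrum.
radial_power <- function(vol) {
  d <- dim(vol)
  pw <- Mod(fft(vol))^2
  fr <- function(n) { k <- seq_len(n) - 1L; k[k > n %/% 2] <- k[k > n %/% 2] - n; k }
  r <- sqrt(outer(outer(fr(d[1])^2, fr(d[2])^2, `+`), fr(d[3])^2, `+`))
  s <- as.integer(round(r))
  keep <- s <= min(d) %/% 2
  tapply(pw[keep], s[keep], mean)
}

tiny_training_pairs <- function(n_cubes = 2, cube = 16, crop = 8, seed = 1) {
  set.seed(seed)
  cubes <- lapply(seq_len(n_cubes), function(i) rand_vol(cube, seed + i))
  build_epoch_dataset(subtomo_set(cubes), wedge_spec(), crop, rng_seed = seed)
}
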