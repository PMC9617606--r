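test_that("the wedge filter matches the tilt-fan geometry voxel by voxel", {
  n <- 32
  w <- wedge_spec()
  filt <- wedge_filter(rep(n, 3), w)
  expect_equal(filt[1, 1, 1], 1)          # DC sampled
  expect_equal(filt[2, 1, 1], 1)          # kx axis: equatorial, sampled
  expect_equal(filt[1, 1, 2], 0)          # kz axis: inside the wedge
  expect_equal(filt[1, 5, 2], 0)          # ky unconstrained
  # brute-force oracle over the full grid
  fr <- function(m) { k <- seq_len(m) - 1L; k[k > m %/% 2] <- k[k > m %/% 2] - m; k }
  kx <- fr(n); kz <- fr(n)
  for (trial in list(c(2, 3, 9), c(30, 7, 2), c(5, 5, 30), c(17, 1, 17))) {
    ang <- atan2(kz[trial[3]], kx[trial[1]]) * 180 / pi
    if (ang > 90) ang <- ang - 180
    if (ang <= -90) ang <- ang + 180
    expect_equal(filt[trial[1], trial[2], trial[3]],
                 as.numeric(ang >= -60 && ang <= 60))
  }
  # zero fraction within the Nyquist disc of the (kx,kz) plane: the missing
  # 2 x 30 degrees of the 180-degree fan occupy exactly 1/3 of directions
  r2 <- outer(kx^2, kz^2, `+`)
  disc <- r2 <= (n / 2)^2 & r2 > 0
  plane <- filt[, 1, ]
  expect_equal(sum(plane[disc] == 0) / sum(disc), 1 / 3, tolerance = 0.02)
})

test_that("the inverse wedge filter is the complement apart from DC", {
  n <- 24
  f <- wedge_filter(rep(n, 3))
  g <- inverse_wedge_filter(rep(n, 3))
  s <- f + g
  expect_equal(s[1, 1, 1], 1)             # DC: 1 + 0
  expect_true(all(s == 1))
  expect_true(all(g[, , 1] == 0))         # equatorial plane never in the wedge
  expect_equal(sum(g == 0), length(g) - sum(f == 0))
})

test_that("Fourier filtering is an identity for all-ones, idempotent, and Parseval-consistent", {
  v <- rand_vol(16, 2)
  ones <- array(1, dim(v))
  expect_equal(apply_fourier_filter(v, ones), v, tolerance = 1e-12)
  filt <- wedge_filter(dim(v))
  once <- apply_fourier_filter(v, filt)
  expect_equal(apply_fourier_filter(once, filt), once, tolerance = 1e-10)
  # output power equals the spectral sum over the passband
  pw <- sum(Mod(fft(v))^2 * filt) / length(v)
  expect_equal(sum(once^2), pw, tolerance = 1e-8)
  expect_error(apply_fourier_filter(v, array(1, c(8, 8, 8))), "mismatch")
})

test_that("the cubic rotation group has 24 distinct proper members closed under composition", {
  rots <- cube_rotations()
  expect_length(rots, 24)
  mats <- lapply(rots, `[[`, "matrix")
  expect_equal(length(unique(lapply(mats, as.vector))), 24)
  expect_true(all(vapply(mats, det, 0) == 1))
  inset <- function(m) any(vapply(mats, function(x) all(x == m), TRUE))
  expect_true(all(vapply(mats, function(a)
    all(vapply(mats, function(b) inset(a %*% b), TRUE)), TRUE)))
  expect_true(inset(diag(3)))
})

test_that("exactly four rotations preserve the symmetric wedge; twenty remain", {
  tr <- training_rotations()
  expect_length(tr, 20)
  excluded <- Filter(function(r)
    !any(vapply(tr, function(t) all(t$matrix == r$matrix), TRUE)),
    cube_rotations())
  expect_length(excluded, 4)
  # the excluded set: identity and the three 180-degree axis rotations
  expected <- list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)),
                   diag(c(-1, -1, 1)))
  for (e in expected)
    expect_true(any(vapply(excluded, function(r) all(r$matrix == e), TRUE)))
  # every kept rotation moves the wedge: filter built from rotated
  # coordinates must differ from the unrotated filter (independent check)
  n <- 16
  fr <- function(m) { k <- seq_len(m) - 1L; k[k > m %/% 2] <- k[k > m %/% 2] - m; k }
  grid <- expand.grid(kx = fr(n), ky = fr(n), kz = fr(n))
  samp <- function(kx, kz) {
    ang <- atan2(kz, kx) * 180 / pi
    ang[ang > 90] <- ang[ang > 90] - 180
    ang[ang <= -90] <- ang[ang <= -90] + 180
    (ang >= -60 & ang <= 60) | (kx == 0 & kz == 0)
  }
  base <- samp(grid$kx, grid$kz)
  for (r in tr) {
    ri <- t(r$matrix)
    rk <- as.matrix(grid) %*% t(ri)
    expect_false(all(samp(rk[, 1], rk[, 3]) == base), info = r$label)
  }
})

test_that("cubic-group volume rotation matches a brute-force voxel loop and is lossless", {
  v <- rand_vol(6, 4)
  for (r in cube_rotations()) {
    expect_identical(rotate_volume(v, r), rotate_brute(v, r$matrix),
                     info = r$label)
    expect_equal(sum(rotate_volume(v, r)), sum(v))
    inv <- list(matrix = t(r$matrix), label = "inv")
    expect_identical(rotate_volume(rotate_volume(v, r), inv), v)
  }
  # four in-plane Z rotations compose to the identity
  rz <- list(matrix = matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3,
                             byrow = TRUE), label = "z90")
  out <- v
  for (i in 1:4) out <- rotate_volume(out, rz)
  expect_identical(out, v)
})

test_that("fourier_merge restores wedge content without touching measured data", {
  w <- wedge_spec()
  gt <- rand_vol(16, 8)
  corrupted <- apply_fourier_filter(gt, wedge_filter(dim(gt), w))
  # complementary supports: merging the truth back restores it
  expect_equal(fourier_merge(corrupted, gt, w), gt, tolerance = 1e-10)
  # zero prediction leaves the original untouched
  expect_equal(fourier_merge(corrupted, array(0, dim(gt)), w), corrupted)
  # sampled-region spectrum of the merge equals the original's
  pred <- rand_vol(16, 9)
  merged <- fourier_merge(corrupted, pred, w)
  filt <- wedge_filter(dim(gt), w)
  fo <- fft(corrupted) * filt
  fm <- fft(merged) * filt
  expect_lt(max(Mod(fm - fo)) / max(Mod(fo)), 1e-10)
  # merging is idempotent: re-merging the merged result onto the original
  # reproduces it (the original's wedge region is empty)
  expect_equal(fourier_merge(corrupted, merged, w), merged, tolerance = 1e-10)
})
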