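test_that("FSC self- and anti-correlation are exactly plus and minus one", {
  x <- rand_vol(32, 1)
  cs <- fsc(x, x)
  expect_true(all(abs(cs$fsc - 1) < 1e-10))
  ca <- fsc(x, -x)
  expect_true(all(abs(ca$fsc + 1) < 1e-10))
  expect_error(fsc(x, rand_vol(16, 1)), "shape")
})

test_that("FSC is symmetric and scale invariant", {
  a <- rand_vol(24, 2); b <- rand_vol(24, 3)
  expect_equal(fsc(a, b)$fsc, fsc(b, a)$fsc, tolerance = 1e-12)
  expect_equal(fsc(a, 5 * b)$fsc, fsc(a, b)$fsc, tolerance = 1e-12)
})

test_that("independent white noise decorrelates at the expected null level", {
  a <- rand_vol(48, 4); b <- rand_vol(48, 5)
  curve <- fsc(a, b)
  bound <- 3 / sqrt(curve$n_voxels)
  expect_gt(mean(abs(curve$fsc) < bound), 0.95)
})

test_that("conical FSC separates directions corrupted by wedge substitution", {
  set.seed(6)
  a <- rand_vol(32, 6)
  # replace only the wedge region of b with independent noise
  w <- wedge_spec()
  inv <- inverse_wedge_filter(dim(a), w)
  b <- apply_fourier_filter(a, 1 - inv) +
    apply_fourier_filter(rand_vol(32, 7), inv)
  cz <- conical_fsc(a, b, c(0, 0, 1), half_angle = 20)
  cx <- conical_fsc(a, b, c(1, 0, 0), half_angle = 20)
  okz <- !is.na(cz$fsc); okx <- !is.na(cx$fsc)
  expect_lt(mean(cz$fsc[okz]), 0.35)     # Z cone sits inside the wedge
  expect_gt(min(cx$fsc[okx]), 0.99)      # X cone untouched
  expect_true(all(abs(conical_fsc(a, a, c(0, 1, 1))$fsc -
                        1 < 1e-10), na.rm = TRUE))
})

test_that("resolution readout interpolates crossings and handles extremes", {
  mk <- function(v, px = 10) {
    df <- data.frame(shell = seq_along(v), freq = seq_along(v) / 32,
                     fsc = v, n_voxels = NA)
    attr(df, "pixel_size") <- px
    class(df) <- c("fsc_curve", "data.frame")
    df
  }
  # constant 1: never crosses, Nyquist resolution 2 * pixel size
  expect_equal(resolution_at(mk(rep(1, 16)), 0.143), 20)
  # step curve: crossing between shells 8 and 9, linear interpolation
  v <- c(rep(1, 8), rep(0, 8))
  curve <- mk(v)
  f_star <- (8 + (1 - 0.5) / 1) / 32
  expect_equal(resolution_at(curve, 0.5), 10 / f_star, tolerance = 1e-12)
  # already below the cutoff everywhere
  low <- resolution_at(mk(rep(0.05, 16)), 0.5)
  expect_true(isTRUE(attr(low, "below_cutoff")))
})

test_that("a band-limited construction reports its designed cutoff frequency", {
  # two volumes share content below f* and are independent above it
  n <- 48
  f_star <- 0.25
  shared <- rand_vol(n, 8)
  d <- rep(n, 3)
  fr <- function(m) { k <- seq_len(m) - 1L; k[k > m %/% 2] <- k[k > m %/% 2] - m; k }
  r <- sqrt(outer(outer((fr(n) / n)^2, (fr(n) / n)^2, `+`), (fr(n) / n)^2, `+`))
  lp <- array(as.numeric(r <= f_star), d)
  a <- apply_fourier_filter(shared, lp) +
    apply_fourier_filter(rand_vol(n, 9), 1 - lp)
  b <- apply_fourier_filter(shared, lp) +
    apply_fourier_filter(rand_vol(n, 10), 1 - lp)
  res <- resolution_at(fsc(a, b, pixel_size = 1), 0.143)
  expect_lt(abs(1 / res - f_star), 1.5 / n)   # within ~one shell width
})

test_that("gold-standard 3D FSC averages matched cubes and flags anisotropy", {
  v <- rand_vol(40, 11)
  same <- gold_standard_3dfsc(v, v, n_cubes = 2, cube = 24)
  # narrow cones miss some low-frequency shells entirely (NA); where
  # defined, identical halves correlate perfectly
  expect_true(all(abs(same$curves - 1) < 1e-8, na.rm = TRUE))
  expect_true(all(same$resolution_143 == 2))   # Nyquist everywhere
  # wedge-substituted pair: Z-ish directions resolve worse than X-ish
  w <- wedge_spec()
  inv <- inverse_wedge_filter(dim(v), w)
  v2 <- apply_fourier_filter(v, 1 - inv) +
    apply_fourier_filter(rand_vol(40, 12), inv)
  res <- gold_standard_3dfsc(v, v2, n_cubes = 2, cube = 24)
  zdir <- which.max(abs(res$directions[, 3]))
  xdir <- which.max(abs(res$directions[, 1]))
  expect_gt(res$resolution_143[zdir], res$resolution_143[xdir])
  # averaging equals the mean of per-cube runs
  r1 <- gold_standard_3dfsc(v, v2, n_cubes = 1, cube = 24)
  expect_equal(dim(res$curves), dim(r1$curves))
})
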