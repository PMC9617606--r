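test_that("the SSNR model evaluates per its definition", {
  p <- deconv_params(snrfalloff = 1, strength = 1, highpass_freq = 0.02)
  # high-pass vanishes at DC regardless of F and S
  expect_equal(ssnr(0, p), 0)
  expect_equal(ssnr(0, deconv_params(snrfalloff = 0, strength = 3)), 0)
  # independent scalar computation at a frequency where H = 1
  f <- 0.05
  expect_equal(ssnr(f, p), exp(-f * 100 * 1) * 10^1 * 1, tolerance = 1e-12)
  # strictly decreasing beyond the high-pass corner when F > 0
  fs <- seq(0.02, 0.5, by = 0.01)
  expect_true(all(diff(ssnr(fs, p)) < 0))
  expect_error(ssnr(-0.1, p), "non-negative")
})

test_that("the CTF has the standard low-frequency and oscillation behaviour", {
  p <- deconv_params(defocus = 2, voltage = 300, cs = 2.7,
                     amplitude_contrast = 0.07, pixel_size = 10)
  expect_equal(ctf_1d(0, p), -0.07, tolerance = 1e-12)
  fs <- seq(0, 0.5, length.out = 2000)
  v <- ctf_1d(fs, p)
  expect_true(all(v >= -1 - 1e-12 & v <= 1 + 1e-12))
  # first zero crossing against an independent bracketing root search
  sgn <- sign(v)
  i <- which(diff(sgn) != 0)[1]
  bracket <- uniroot(function(f) ctf_1d(f, p), c(fs[i], fs[i + 1]),
                     tol = 1e-10)$root
  # oracle: chi at the zero satisfies tan(chi) = -A/sqrt(1-A^2)
  lambda <- 12.2639 / sqrt(300e3 + 0.97845e-6 * (300e3)^2)
  chi <- function(fA) pi * lambda * 2e4 * fA^2 - pi / 2 * 2.7e7 * lambda^3 * fA^4
  A <- 0.07
  chi_star <- pi - atan(A / sqrt(1 - A^2))  # first solution with CTF = 0
  froot <- uniroot(function(fA) chi(fA) - chi_star, c(1e-4, 0.08),
                   tol = 1e-12)$root
  expect_equal(bracket, froot * 10, tolerance = 1e-4)
})

test_that("Wiener deconvolution is linear, preserves DC and shapes noise by |W|^2", {
  p <- deconv_params(defocus = 3, pixel_size = 10, strength = 1,
                     snrfalloff = 0.5)
  v1 <- rand_vol(24, 1); v2 <- rand_vol(24, 2)
  d12 <- deconvolve(2 * v1 - 3 * v2, p)
  expect_equal(d12, 2 * deconvolve(v1, p) - 3 * deconvolve(v2, p),
               tolerance = 1e-10)
  expect_equal(mean(deconvolve(v1, p)), mean(v1), tolerance = 1e-10)
  expect_identical(dim(d12), dim(v1))
  # white noise in, radial power out ~ |W(f)|^2
  n <- 48
  wn <- rand_vol(n, 9)
  out <- deconvolve(wn, p)
  rp <- radial_power(out)
  rp_in <- radial_power(wn)
  shells <- as.numeric(names(rp))
  w2 <- tomowedge:::wiener_gain(shells / n, p)^2
  sel <- shells >= 2  # skip DC/first shell (few voxels, DC exempt)
  # per-shell output power = |W|^2 times input power (W varies slightly
  # within each one-voxel shell, so compare with a generous median)
  ratio <- rp[sel] / (w2[sel] * rp_in[sel])
  expect_true(stats::median(abs(ratio - 1)) < 0.1)
})

test_that("density and std masks keep the requested fractions and regions", {
  v <- rand_vol(48, 5)
  p <- mask_params(density_percentage = 50, std_percentage = 50)
  m <- density_mask(v, p)
  expect_equal(mean(m), 0.5, tolerance = 0.01)
  expect_true(all(density_mask(v, mask_params(density_percentage = 100))))
  expect_true(all(std_mask(v, mask_params(std_percentage = 100))))
  expect_warning(std_mask(array(1, rep(16, 3)), p), "empty")
  # a bright (dense, i.e. dark before inversion) blob is kept
  blob <- array(0, rep(32, 3))
  blob[14:18, 14:18, 14:18] <- -10
  mb <- density_mask(blob, mask_params(density_percentage = 5))
  expect_true(mb[16, 16, 16])
  expect_lt(mean(mb), 0.07)
  # flat half vs textured half: std mask picks the textured one
  half <- array(0, c(32, 32, 32))
  set.seed(11)
  half[17:32, , ] <- rnorm(16 * 32 * 32)
  ms <- std_mask(half, mask_params(std_percentage = 50))
  expect_gt(sum(ms[17:32, , ]) / sum(ms), 0.95)
})

test_that("the combined mask is the intersection with z-cropping", {
  v <- rand_vol(40, 7)
  p100 <- mask_params(density_percentage = 100, std_percentage = 100)
  expect_true(all(make_mask(v, p100)))
  pz <- mask_params(density_percentage = 100, std_percentage = 100,
                    z_crop = 0.1)
  mz <- make_mask(v, pz)   # 40 slices: 4 cropped top and bottom
  expect_false(any(mz[, , c(1:4, 37:40)]))
  expect_true(all(mz[, , 5:36]))
  p <- mask_params(density_percentage = 40, std_percentage = 60)
  m <- make_mask(v, p)
  expect_true(all(m <= density_mask(v, p)))
  expect_true(all(m <= std_mask(v, p)))
})
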