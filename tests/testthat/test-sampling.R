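test_that("seed sampling is reproducible, in-bounds and mask-respecting", {
  mask <- array(TRUE, c(40, 40, 40))
  s1 <- sample_seeds(mask, 10, cube_size = 16, rng_seed = 3)
  s2 <- sample_seeds(mask, 10, cube_size = 16, rng_seed = 3)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 10)
  # margin: a 16-cube centred at the seed must fit
  expect_true(all(s1 >= 8 & s1 <= 32))
  # support restriction: seeds only where the mask is true
  oct <- array(FALSE, c(40, 40, 40))
  oct[1:20, 1:20, 1:20] <- TRUE
  so <- sample_seeds(oct, 25, cube_size = 8, rng_seed = 1)
  expect_true(all(so <= 20))
  expect_error(sample_seeds(oct, 1e6, cube_size = 8, rng_seed = 1),
               "eligible")
})

test_that("percentile normalization brackets 90% of voxels in (0,1) and inverts", {
  v <- rand_vol(64, 6)
  nv <- normalize_percentile(v)
  frac <- mean(nv > 0 & nv < 1)
  expect_equal(frac, 0.9, tolerance = 2 / length(v) + 1e-6)
  # affine invariance
  expect_equal(normalize_percentile(3 * v + 7), nv, tolerance = 1e-9,
               ignore_attr = TRUE)
  # recorded inverse transform recovers the input
  expect_equal(denormalize(nv), v, tolerance = 1e-9)
  expect_error(normalize_percentile(array(2, rep(8, 3))), "degenerate")
})

test_that("extraction crops inverted, normalized cubes and splits halves evenly", {
  tomo <- tomogram(rand_vol(48, 2), pixel_size = 13.66, name = "x")
  set <- extract_subtomograms(tomo, NULL, count = 11, cube_size = 16,
                              rng_seed = 5, split = TRUE)
  expect_length(set$cubes, 11)
  expect_true(all(vapply(set$cubes, function(c) all(dim(c) == 16), TRUE)))
  expect_equal(sort(as.integer(table(set$half_id))), c(5L, 6L))
  # crop identity: each cube is the normalized negation of its source region
  i <- 4
  s <- set$seeds[i, ]
  region <- tomo$data[s[1] + (-7:8), s[2] + (-7:8), s[3] + (-7:8)]
  expect_equal(set$cubes[[i]], normalize_percentile(-region),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("training pairs are wedge-filtered rotations cropped after filtering", {
  w <- wedge_spec()
  cube <- rand_vol(16, 3)
  r <- training_rotations(w)[[5]]
  pair <- make_training_pair(cube, r, w, crop_size = 8)
  expect_identical(dim(pair$input), dim(pair$target))
  # cropping AFTER filtering: reproduce by hand
  rot <- rotate_volume(cube, r)
  filt <- wedge_filter(dim(rot), w)
  expect_equal(pair$target, tomowedge:::center_crop(rot, 8))
  expect_equal(pair$input,
               tomowedge:::center_crop(apply_fourier_filter(rot, filt), 8),
               tolerance = 1e-12)
  # filtering removes power
  expect_lte(sum(pair$input^2), sum(pair$target^2) + 1e-9)
  expect_error(make_training_pair(cube, r, w, crop_size = 32), "exceeds")
})

test_that("an epoch dataset is the balanced shuffled cube-rotation product", {
  cubes <- subtomo_set(lapply(1:3, function(i) rand_vol(12, i)))
  pairs <- build_epoch_dataset(cubes, wedge_spec(), crop_size = 8,
                               rng_seed = 9)
  expect_length(pairs, 60)   # 3 cubes x 20 rotations
  labels <- vapply(pairs, function(p) p$rotation$label, "")
  expect_true(all(table(labels) == 3))
  src <- vapply(pairs, function(p) p$source_index, 0L)
  expect_true(all(table(src) == 20))
  pairs2 <- build_epoch_dataset(cubes, wedge_spec(), crop_size = 8,
                                rng_seed = 9)
  expect_identical(vapply(pairs2, function(p) p$rotation$label, ""), labels)
  # supervised mapping is exactly "remove an extra wedge": filtering the
  # target reproduces the input (within crop-edge tolerance this is exact
  # because both were filtered before cropping)
  p1 <- make_training_pair(cubes$cubes[[1]],
                           training_rotations(wedge_spec())[[1]],
                           wedge_spec(), 12)
  refiltered <- apply_fourier_filter(p1$target, wedge_filter(dim(p1$target)))
  expect_equal(refiltered, p1$input, tolerance = 1e-10)
})
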