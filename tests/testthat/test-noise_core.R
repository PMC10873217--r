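test_that("block_sd implements the n-1 sample SD", {
  expect_identical(block_sd(rep(3.7, 64)), 0)
  # 32 zeros + 32 twos: mean 1, sum of squares 64, variance 64/63
  expect_equal(block_sd(c(rep(0, 32), rep(2, 32))), sqrt(64 / 63),
               tolerance = 1e-12)
  expect_error(block_sd(1.5), "degenerate block")

  set.seed(8)
  draws <- rnorm(10000, mean = 1, sd = 0.3)
  mc_se <- 0.3 / sqrt(2 * (10000 - 1))
  expect_lt(abs(block_sd(draws) - 0.3), 3 * mc_se)
})

test_that("slice_noise_map tiles, truncates and flags validity", {
  sl <- matrix(2.0, 16, 16)
  nm <- slice_noise_map(sl, matrix(TRUE, 16, 16), block_size = 8)
  expect_equal(dim(nm$values), c(2L, 2L))
  expect_true(all(nm$valid))
  expect_true(all(nm$values == 0))

  # trailing partial row dropped, no padding
  nm17 <- slice_noise_map(matrix(1, 17, 16), matrix(TRUE, 17, 16))
  expect_equal(dim(nm17$values), c(2L, 2L))

  # 31 of 64 in-mask pixels < 50% -> invalid
  m <- matrix(FALSE, 8, 8); m[seq_len(31)] <- TRUE
  nm31 <- slice_noise_map(matrix(rnorm(64), 8, 8), m)
  expect_false(nm31$valid[1, 1])
  expect_true(is.na(nm31$values[1, 1]))
  # 32 of 64 is enough, SD over in-mask pixels only
  m32 <- matrix(FALSE, 8, 8); m32[seq_len(32)] <- TRUE
  sl32 <- matrix(rnorm(64), 8, 8)
  nm32 <- slice_noise_map(sl32, m32)
  expect_true(nm32$valid[1, 1])
  expect_identical(nm32$values[1, 1], block_sd(sl32[m32]))

  expect_error(slice_noise_map(matrix(1, 4, 4), matrix(TRUE, 4, 4)),
               "slice too small")
})

test_that("macro pixels equal the brute-force oracle exactly", {
  set.seed(21)
  for (case in 1:4) {
    nr <- sample(17:40, 1); nc <- sample(17:40, 1)
    sl <- matrix(rnorm(nr * nc, 1, 0.3), nr, nc)
    m <- random_blob_mask(nr, nc, n_blobs = 3, seed = case)
    for (bs in c(4L, 8L)) {
      got <- slice_noise_map(sl, m, block_size = bs, min_valid_fraction = 0.5)
      want <- oracle_noise_map(sl, m, bs, 0.5)
      expect_identical(got$valid, want$valid)
      expect_identical(got$values, want$values)
    }
  }
})

test_that("histogram counts conserve the valid macro-pixel total", {
  spec <- small_phantom_spec(sigma_ref = 0.2)
  ph <- make_phantom(spec, bed_time_s = 60, seed = 5)
  mask <- tissue_mask(ph$volume)
  maps <- volume_noise_maps(ph$volume, mask)
  h <- noise_histogram(maps)
  n_valid_per_slice <- vapply(maps, function(nm) sum(nm$valid), integer(1))
  expect_identical(sum(h$counts), h$n_total)
  expect_identical(h$n_total, sum(n_valid_per_slice))
  # uniform, strictly increasing, left edge at 0
  expect_equal(h$bin_edges[1], 0)
  expect_equal(diff(h$bin_edges), rep(h$bin_width, length(h$counts)))
})

test_that("noise_histogram bins left-closed right-open from zero", {
  nm <- structure(list(values = matrix(c(0.005, 0.005, 0.012, NA), 2, 2),
                       valid = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2),
                       block_size = 8L, slice_index = 1L),
                  class = "noise_map")
  h <- noise_histogram(nm, bin_width = 0.01)
  expect_equal(h$counts, c(2L, 1L))
  expect_equal(h$bin_edges, c(0, 0.01, 0.02))

  empty <- structure(list(values = matrix(NA_real_, 1, 1),
                          valid = matrix(FALSE, 1, 1),
                          block_size = 8L, slice_index = 1L),
                     class = "noise_map")
  expect_error(noise_histogram(empty), "no noise samples")
})

test_that("right-skewed samples put the mean above the mode bin", {
  set.seed(31)
  vals <- rgamma(1e5, shape = 2, rate = 20)
  nm <- structure(list(values = matrix(vals, nrow = 1),
                       valid = matrix(TRUE, 1, length(vals)),
                       block_size = 8L, slice_index = 1L),
                  class = "noise_map")
  h <- noise_histogram(nm, bin_width = 0.01)
  expect_gt(mean(vals), histogram_mode(h))
})

test_that("histogram_mode takes the first maximal bin center", {
  h <- structure(list(bin_width = 0.1, bin_edges = c(0, 0.1, 0.2, 0.3),
                      counts = c(1L, 5L, 2L), n_total = 8L),
                 class = "noise_histogram")
  expect_equal(histogram_mode(h), 0.15)
  h$counts <- c(3L, 3L, 0L); h$n_total <- 6L
  expect_equal(histogram_mode(h), 0.05)   # tie -> lowest bin

  set.seed(41)
  draws <- abs(rnorm(1e6, 0.30, 0.01))
  nm <- structure(list(values = matrix(draws, nrow = 1),
                       valid = matrix(TRUE, 1, length(draws)),
                       block_size = 8L, slice_index = 1L),
                  class = "noise_map")
  mode <- histogram_mode(noise_histogram(nm, bin_width = 0.01))
  expect_true(mode %in% c(0.295, 0.305))
})

test_that("a noiseless phantom has GNI in the lowest bin", {
  spec <- small_phantom_spec(sigma_ref = 0)
  ph <- make_phantom(spec, bed_time_s = 120, seed = 1)
  g <- global_noise_index(ph$volume)
  expect_equal(g$gni, 0.005)
  # mode is the center of a maximal-count bin
  i <- which.max(g$histogram$counts)
  expect_equal(g$gni,
               mean(g$histogram$bin_edges[c(i, i + 1)]))
})

test_that("GNI recovers sigma on a homogeneous noise volume", {
  vol <- homogeneous_volume(c(96, 96, 40), sigma = 0.3, seed = 6)
  g <- global_noise_index(vol)
  expect_lt(abs(g$gni - 0.3), 0.02)
  expect_gte(g$gni, 0)
})

test_that("GNI is shift invariant and scale equivariant", {
  spec <- small_phantom_spec(sigma_ref = 0.18)
  ph <- make_phantom(spec, bed_time_s = 90, seed = 7)
  vol <- ph$volume
  mask <- tissue_mask(vol)
  g0 <- global_noise_index(vol, mask = mask)

  # shift: add a constant to tissue voxels, mask unchanged
  shifted <- vol
  shifted$voxels[mask$mask] <- shifted$voxels[mask$mask] + 2.0
  g_shift <- global_noise_index(shifted, mask = mask)
  expect_identical(g_shift$gni, g0$gni)
  expect_identical(g_shift$histogram$counts, g0$histogram$counts)

  # scale voxels and threshold together
  a <- 2.7
  scaled <- vol
  scaled$voxels <- scaled$voxels * a
  g_scale <- global_noise_index(scaled, threshold = 0.15 * a)
  expect_lte(abs(g_scale$gni - a * g0$gni), a * 0.01 + 1e-12)  # one bin width

})

test_that("rerunning the pipeline is bit-identical", {
  spec <- small_phantom_spec(sigma_ref = 0.15)
  ph <- make_phantom(spec, bed_time_s = 30, seed = 9)
  g1 <- global_noise_index(ph$volume)
  g2 <- global_noise_index(ph$volume)
  expect_identical(g1$gni, g2$gni)
  expect_identical(g1$histogram$counts, g2$histogram$counts)
})

test_that("slicewise GNI tracks homogeneous noise and flags empty slices", {
  vol <- homogeneous_volume(c(64, 64, 12), sigma = 0.2, seed = 10)
  # append two air-only slices
  vox <- array(0, c(64, 64, 14))
  vox[, , 1:12] <- vol$voxels
  vol2 <- suv_volume(vox, spacing = vol$spacing)
  s <- slicewise_gni(vol2)
  expect_length(s$gni, 14)
  expect_true(all(is.na(s$gni[13:14])))
  expect_true(all(abs(s$gni[1:12] - 0.2) <= 0.03))
})

test_that("a sigma step between volume halves appears in the series", {
  v1 <- homogeneous_volume(c(64, 64, 10), sigma = 0.1, seed = 11)
  v2 <- homogeneous_volume(c(64, 64, 10), sigma = 0.3, seed = 12)
  vox <- array(0, c(64, 64, 20))
  vox[, , 1:10] <- v1$voxels
  vox[, , 11:20] <- v2$voxels
  vol <- suv_volume(vox)
  s <- slicewise_gni(vol, slab_thickness = 5)
  expect_length(s$gni, 4)
  # per-half whole-volume GNI as oracle for the step levels
  g1 <- global_noise_index(v1)$gni
  g2 <- global_noise_index(v2)$gni
  expect_true(all(abs(s$gni[1:2] - g1) <= 0.02))
  expect_true(all(abs(s$gni[3:4] - g2) <= 0.03))
  expect_gt(min(s$gni[3:4]) - max(s$gni[1:2]), 0.1)
})

test_that("noise maps export as a reduced-matrix volume", {
  vol <- homogeneous_volume(c(32, 32, 4), sigma = 0.2, seed = 13)
  mask <- tissue_mask(vol)
  maps <- volume_noise_maps(vol, mask)
  nmvol <- noise_maps_as_volume(maps, vol)
  expect_equal(dim(nmvol$voxels), c(4, 4, 4))
  expect_equal(nmvol$spacing, vol$spacing * c(8, 8, 1))
  p <- tempfile(fileext = ".nii.gz")
  write_nifti(nmvol, p)
  expect_identical(read_nifti(p)$voxels, nmvol$voxels)
  unlink(p)
})
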