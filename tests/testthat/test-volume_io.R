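test_that("suv_bw matches its definition and decays correctly", {
  # unit-consistent reference concentration -> SUV exactly 1
  decayed <- 249.3 * 2^(-58.7 / 109.77)   # hand application of the formula
  ref_conc <- decayed / 70
  expect_equal(suv_bw(ref_conc, 70, 249.3, 58.7), 1.0)
  expect_equal(suv_bw(ref_conc / 2, 70, 249.3, 58.7), 0.5)
  expect_equal(suv_bw(0, 70, 249.3, 58.7), 0.0)
  # no uptake time -> no decay
  expect_equal(suv_bw(10, 50, 100, 0), 10 / (100 / 50))
})

test_that("suv_bw is linear in concentration and rejects bad metadata", {
  c0 <- 3.7
  expect_equal(suv_bw(5 * c0, 80, 200, 45), 5 * suv_bw(c0, 80, 200, 45))
  # doubling activity and the weight-normalized reference simultaneously
  expect_equal(suv_bw(2 * c0, 70, 2 * 250, 30), suv_bw(c0, 70, 250, 30))
  expect_error(suv_bw(1, 0, 100, 30), "invalid metadata")
  expect_error(suv_bw(1, 70, -5, 30), "invalid metadata")
  expect_error(suv_bw(1, 70, 100, -1), "invalid metadata")
})

test_that("NIfTI write -> read round-trips voxels and geometry exactly", {
  set.seed(11)
  vol <- suv_volume(array(rnorm(16 * 16 * 4), c(16, 16, 4)),
                    spacing = c(2.5, 2.5, 3.3), origin = c(-20, -10.5, 4))
  for (ext in c(".nii", ".nii.gz")) {
    p <- tempfile(fileext = ext)
    write_volume(vol, p)
    back <- read_volume(p)
    expect_identical(back$voxels, vol$voxels)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)  # float32 header
    expect_equal(back$origin, vol$origin, tolerance = 1e-6)
    unlink(p)
  }
})

test_that("an all-ones NIfTI reads back as an all-ones volume", {
  p <- tempfile(fileext = ".nii")
  write_nifti(suv_volume(array(1, c(16, 16, 4)), spacing = c(2, 2, 2)), p)
  v <- read_volume(p, format_hint = "nifti")
  expect_true(all(v$voxels == 1.0))
  expect_equal(v$spacing, c(2, 2, 2), tolerance = 1e-6)
  unlink(p)
})

test_that("our NIfTI agrees with an independent reader (nibabel)", {
  set.seed(5)
  vol <- suv_volume(array(round(rnorm(6 * 5 * 4), 6), c(6, 5, 4)),
                    spacing = c(2, 3, 4), origin = c(1, -2, 3))
  p <- tempfile(fileext = ".nii.gz")
  write_nifti(vol, p)
  script <- sprintf(paste0(
    "import nibabel as nib, numpy as np\n",
    "img = nib.load('%s')\n",
    "d = np.asarray(img.dataobj)\n",
    "print(d.shape[0], d.shape[1], d.shape[2])\n",
    "print(repr(float(d.sum())))\n",
    "print(repr(float(d[0,0,0])), repr(float(d[5,4,3])))\n",
    "print(*img.header.get_zooms())\n"), p)
  out <- tryCatch(
    system2("python", "-", input = script, stdout = TRUE, stderr = FALSE),
    error = function(e) NULL
  )
  expect_false(is.null(out))
  expect_equal(scan(text = out[1], quiet = TRUE), dim(vol$voxels))
  expect_equal(scan(text = out[2], quiet = TRUE), sum(vol$voxels))
  corner <- scan(text = out[3], quiet = TRUE)
  expect_equal(corner, c(vol$voxels[1, 1, 1], vol$voxels[6, 5, 4]))
  expect_equal(scan(text = out[4], quiet = TRUE), c(2, 3, 4), tolerance = 1e-6)
  unlink(p)
})

write_test_series <- function(dir, n_slices = 3, pixel_value = 1000L,
                              weight = 70, dose_Bq = 249.3e6,
                              uptake_min = 60, dz = 3.3, dims = c(16, 16),
                              uid = "1.2.826.0.1.999", z0 = 0,
                              series_time = "110000") {
  dir.create(dir, showWarnings = FALSE)
  conc_Bq_ml <- dose_Bq * 2^(-uptake_min / 109.77) / (weight * 1000)
  slope <- conc_Bq_ml / pixel_value
  for (k in seq_len(n_slices)) {
    petgni:::write_dicom_slice(
      file.path(dir, sprintf("sl%02d.dcm", k)),
      matrix(pixel_value, dims[1], dims[2]),
      slice_z = z0 + (k - 1) * dz, pixel_spacing = c(2.5, 2.5),
      slice_thickness = dz, series_uid = uid, instance = k,
      units = "BQML", rescale_slope = slope,
      weight_kg = weight, dose_Bq = dose_Bq,
      injection_time = "100000", series_time = series_time
    )
  }
  dir
}

test_that("a synthetic BQML DICOM series converts to SUV 1.0", {
  dir <- write_test_series(tempfile("dcm"))
  vol <- read_volume(dir, format_hint = "dicom_series")
  expect_equal(dim(vol$voxels), c(16L, 16L, 3L))
  # rescale slope passes through a decimal-string header field
  expect_equal(max(abs(vol$voxels - 1)), 0, tolerance = 1e-5)
  expect_equal(vol$spacing, c(2.5, 2.5, 3.3), tolerance = 1e-9)
  expect_equal(vol$meta$weight_kg, 70)
  expect_equal(vol$meta$uptake_time_min, 60)
  unlink(dir, recursive = TRUE)
})

test_that("DICOM pixel orientation survives the row-major round trip", {
  dir <- tempfile("dcm")
  dir.create(dir)
  px <- matrix(seq_len(12 * 10), nrow = 12, ncol = 10)   # asymmetric pattern
  petgni:::write_dicom_slice(
    file.path(dir, "s1.dcm"), px, slice_z = 0, pixel_spacing = c(2, 2),
    slice_thickness = 3, series_uid = "1.2.3", instance = 1, units = "GML",
    rescale_slope = 1
  )
  vol <- read_dicom_series(dir)
  expect_equal(vol$voxels[, , 1], px + 0)   # GML: passthrough, no conversion
  unlink(dir, recursive = TRUE)
})

test_that("DICOM series errors are explicit", {
  # two series UIDs in one directory
  dir <- write_test_series(tempfile("dcm"))
  petgni:::write_dicom_slice(
    file.path(dir, "alien.dcm"), matrix(0L, 16, 16), slice_z = 50,
    pixel_spacing = c(2.5, 2.5), slice_thickness = 3.3,
    series_uid = "9.9.9", instance = 1, units = "GML"
  )
  expect_error(read_dicom_series(dir), "ambiguous input")
  unlink(dir, recursive = TRUE)

  # non-uniform slice spacing
  dir <- write_test_series(tempfile("dcm"), n_slices = 2)
  petgni:::write_dicom_slice(
    file.path(dir, "sl03.dcm"), matrix(1000L, 16, 16), slice_z = 11,
    pixel_spacing = c(2.5, 2.5), slice_thickness = 3.3,
    series_uid = "1.2.826.0.1.999", instance = 3, units = "BQML",
    rescale_slope = 1, weight_kg = 70, dose_Bq = 249.3e6
  )
  expect_error(read_dicom_series(dir), "inconsistent geometry")
  unlink(dir, recursive = TRUE)

  # BQML without the SUV metadata
  dir <- tempfile("dcm")
  dir.create(dir)
  petgni:::write_dicom_slice(
    file.path(dir, "s1.dcm"), matrix(10L, 16, 16), slice_z = 0,
    pixel_spacing = c(2.5, 2.5), slice_thickness = 3.3,
    series_uid = "1.2.3", instance = 1, units = "BQML"
  )
  expect_error(read_dicom_series(dir), "metadata incomplete")
  unlink(dir, recursive = TRUE)
})

test_that("reports serialize and round-trip numeric fields bit-exactly", {
  vol <- homogeneous_volume(c(32, 32, 8), sigma = 0.17, seed = 3)
  g <- global_noise_index(vol)
  roc <- roc_analysis(c(0.11, 0.19, 0.23, 0.31, 0.27, 0.13),
                      c("sufficient", "sufficient", "insufficient",
                        "insufficient", "insufficient", "sufficient"))
  p <- tempfile(fileext = ".json")
  write_report(list(gni = g, roc = roc), p)
  back <- read_report(p)
  # JSON is typeless for whole numbers, so compare as numerics
  expect_identical(as.numeric(back$gni$gni), g$gni)
  expect_identical(as.numeric(back$gni$n_macro_pixels), as.numeric(g$n_macro_pixels))
  expect_identical(as.numeric(back$gni$bin_width), g$histogram$bin_width)
  expect_identical(as.numeric(back$roc$auc), roc$auc)
  expect_identical(as.numeric(back$roc$youden_cutoff), roc$youden_cutoff)
  unlink(p)

  expect_error(write_report(list(), tempfile()), "io error")
})

test_that("volume container enforces its invariants", {
  expect_error(suv_volume(array(c(1, NA, 1, 1), c(2, 2, 1))), "finite")
  expect_error(suv_volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(suv_volume(matrix(1, 2, 2)), "3-D")
})
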