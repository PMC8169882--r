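test_that("NIfTI and NRRD volumes round-trip grid, spacing, origin and data", {
  v <- volume(array(rnorm(5 * 4 * 3), c(5, 4, 3)),
              spacing = c(0.5, 0.5, 3.0), origin = c(1, -2, 4.5))
  for (ext in c(".nii.gz", ".nii", ".nrrd")) {
    path <- withr::local_tempfile(fileext = ext)
    write_volume(v, path)
    r <- read_volume(path)
    expect_identical(dim(r), dim(v))
    expect_equal(r$spacing, v$spacing)
    expect_equal(r$origin, v$origin)
    expect_equal(r$data, v$data)
  }
})

test_that("advertised header spacing is passed through", {
  v <- volume(array(0, c(4, 4, 2)), spacing = c(0.5, 0.5, 3.0))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  expect_equal(read_volume(path)$spacing, c(0.5, 0.5, 3.0))
})

test_that("label maps round-trip including the unlabeled sentinel", {
  lab <- label_map(array(c(UNLABELED, 0L, 1L, 2L, 3L, 0L, 1L, 2L), c(2, 2, 2)),
                   spacing = c(1, 1, 3))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(lab, path)
  r <- read_label_map(path)
  expect_identical(r$data, lab$data)
})

test_that("missing files and unsupported formats raise I/O errors naming the path", {
  expect_error(read_volume("/nonexistent/vol.nii.gz"), "nonexistent",
               class = "segda_io_error")
  v <- volume(array(0, c(4, 4, 2)))
  expect_error(write_volume(v, "/nonexistent/dir/vol.nii.gz"),
               class = "segda_io_error")
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines("x", path)
  expect_error(read_volume(path), class = "segda_io_error")
})

test_that("resampling follows the round(dim * spacing / target) dimension rule", {
  # 640 voxels at 0.27 mm resampled to 0.5 mm -> round(640*0.27/0.5) = 346
  v <- volume(array(rnorm(640 * 8 * 2), c(640, 8, 2)),
              spacing = c(0.27, 0.5, 3.0))
  r <- resample(v, c(0.5, 0.5, 3.0))
  expect_identical(dim(r), c(346L, 8L, 2L))
  expect_equal(r$spacing, c(0.5, 0.5, 3.0))
})

test_that("resampling to the input spacing is the identity", {
  v <- volume(array(rnorm(6 * 6 * 4), c(6, 6, 4)), spacing = c(1, 1, 3))
  r <- resample(v, c(1, 1, 3))
  expect_equal(r$data, v$data)
})

test_that("nearest-neighbour label resampling never invents labels", {
  lab <- label_map(array(sample(c(UNLABELED, 0:3), 6 * 6 * 4, TRUE), c(6, 6, 4)),
                   spacing = c(1, 1, 3))
  r <- resample(lab, c(0.7, 1.3, 2.0))
  expect_true(all(r$data %in% unique(as.integer(lab$data))))
  expect_error(resample(lab, c(1, 1, 1), mode = "linear"),
               class = "segda_usage_error")
})

test_that("resample round-trip restores dimensions when divisions are exact", {
  v <- volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 2))
  down <- resample(v, c(2, 2, 2))
  back <- resample(down, c(1, 1, 2))
  expect_identical(dim(back), dim(v))
})

test_that("center cropping keeps the center and pads undersized axes", {
  a <- array(rnorm(30 * 30 * 10), c(30, 30, 10))
  v <- volume(a, spacing = c(1, 1, 3))
  cr <- crop_center(v, c(20, 20, 4))
  expect_identical(dim(cr), c(20L, 20L, 4L))
  # center voxel preserved: input (16,16,6) -> output (11,11,3)
  expect_equal(cr$data[11, 11, 3], a[16, 16, 6])
  expect_equal(crop_center(v, dim(v$data))$data, v$data)
  padded <- crop_center(v, c(40, 30, 10))
  expect_identical(dim(padded), c(40L, 30L, 10L))
  expect_true(all(padded$data[1:5, , ] == 0))
  lab <- label_map(array(1L, c(4, 4, 2)))
  plab <- crop_center(lab, c(6, 4, 2))
  expect_true(all(plab$data[c(1, 6), , ] == 0L))  # background padding
})

test_that("intensity normalization follows the MRI and CT recipes", {
  set.seed(1)
  ramp <- volume(array(seq(0, 1000, length.out = 512), c(8, 8, 8)))
  n <- normalize(ramp, "mri_percentile")
  expect_equal(min(n$data), 0)
  expect_equal(max(n$data), 1)
  # monotone on the clipped range
  expect_true(all(diff(as.numeric(n$data)) >= 0))

  ct <- volume(array(rnorm(512, 0, 400), c(8, 8, 8)))
  nct <- normalize(ct, "ct_window")
  expect_equal(mean(nct$data), 0, tolerance = 1e-12)
  expect_equal(sd(nct$data), 1, tolerance = 1e-12)
  # values beyond the window are clipped before standardization
  big <- volume(array(c(rep(0, 511), 500), c(8, 8, 8)))
  clip <- normalize(big, "ct_window")
  expect_equal(max(clip$data),
               (300 - mean(pmin(pmax(big$data, -300), 300))) /
                 sd(pmin(pmax(big$data, -300), 300)))

  const <- volume(array(5, c(8, 8, 8)))
  expect_true(all(normalize(const, "mri_percentile")$data == 0))
  expect_true(all(normalize(const, "ct_window")$data == 0))
})

test_that("flip augmentation is an involution preserving label counts", {
  cs <- tiny_case(seed = 3)
  once <- augment(cs$volume, cs$labels, "mri_flip")
  twice <- augment(once$volume, once$labels, "mri_flip")
  expect_equal(twice$volume$data, cs$volume$data)
  expect_identical(twice$labels$data, cs$labels$data)
  expect_identical(table(once$labels$data), table(cs$labels$data))
})

test_that("ct_full augmentation with zero magnitudes is the identity", {
  cs <- tiny_case(seed = 4)
  out <- augment(cs$volume, cs$labels, "ct_full", seed = 1,
                 translate_max = 0, scale_range = 0, noise_sigma = 0,
                 blur_sigma_max = 0)
  expect_equal(out$volume$data, cs$volume$data)
  expect_identical(out$labels$data, cs$labels$data)
})

test_that("augmentation never produces label values outside the class set", {
  cs <- tiny_case(seed = 5)
  for (s in 1:5) {
    out <- augment(cs$volume, cs$labels, "ct_full", seed = s,
                   translate_max = 3, scale_range = 0.2, noise_sigma = 0.05,
                   blur_sigma_max = 1)
    expect_true(all(out$labels$data %in% c(UNLABELED, 0:3)))
  }
  mismatched <- label_map(array(0L, c(8, 8, 2)))
  expect_error(augment(cs$volume, mismatched, "mri_flip"),
               class = "segda_usage_error")
})
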