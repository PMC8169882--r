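test_that("phantom generation is deterministic in the seed", {
  cfg <- tiny_phantom_config()
  a <- generate_case(cfg, "source", seed = 11)
  b <- generate_case(cfg, "source", seed = 11)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$data, b$labels$data)
  c2 <- generate_case(cfg, "source", seed = 12)
  expect_false(identical(a$volume$data, c2$volume$data))
})

test_that("labels form a partition with all four classes present", {
  cfg <- tiny_phantom_config(c(24, 24, 8))
  for (s in c(1, 2, 3)) {
    for (dom in c("source", "target")) {
      cs <- generate_case(cfg, dom, seed = s)
      expect_setequal(unique(as.integer(cs$labels$data)), 0:3)
      # integer label per voxel: classes disjoint, background the complement
      expect_identical(dim(cs$labels$data), dim(cs$volume$data))
    }
  }
})

test_that("identity shift makes target output bit-identical to source", {
  cfg <- tiny_phantom_config()
  ident <- domain_shift_config(deformation_amplitude = 0, intensity_gain = 1,
                               intensity_offset = 0, contrast_gamma = 1,
                               extra_noise_sigma = 0)
  src <- generate_case(cfg, "source", seed = 9)
  tgt <- generate_case(cfg, "target", shift = ident, seed = 9)
  expect_identical(src$volume$data, tgt$volume$data)
  expect_identical(src$labels$data, tgt$labels$data)
})

test_that("the domain shift moves labels with the image", {
  cfg <- tiny_phantom_config(c(24, 24, 8))
  shift <- domain_shift_config(extra_noise_sigma = 0)
  tgt <- generate_case(cfg, "target", shift = shift, seed = 21)
  src <- generate_case(cfg, "source", seed = 21)
  # structures moved relative to the source
  expect_false(identical(src$labels$data, tgt$labels$data))
  # but image statistics inside each warped class stay coherent: every
  # foreground class mean remains separated from background
  means <- vapply(0:3, function(cl) mean(tgt$volume$data[tgt$labels$data == cl]), 0)
  expect_true(all(abs(means[2:4] - means[1]) >
                    0.5 * cfg$noise_sigma * shift$intensity_gain))
})

test_that("foreground classes are statistically separable from background", {
  cfg <- tiny_phantom_config(c(24, 24, 8))
  cs <- generate_case(cfg, "source", seed = 5)
  means <- vapply(0:3, function(cl) mean(cs$volume$data[cs$labels$data == cl]), 0)
  expect_true(all(abs(means[2:4] - means[1]) >= 2 * cfg$noise_sigma))
})

test_that("misconfigured geometry raises a configuration error", {
  expect_error(phantom_config(grid_size = c(4, 4, 4)),
               class = "segda_config_error")
  expect_error(phantom_config(grid_size = c(16, 16, 4),
                              blob_semiaxes = c(10, 10, 3)),
               class = "segda_config_error")
  expect_error(domain_shift_config(deformation_amplitude = 0.5),
               class = "segda_config_error")
  expect_error(domain_shift_config(intensity_gain = -1),
               class = "segda_config_error")
})

test_that("cohorts have the requested split structure", {
  cfg <- tiny_phantom_config()
  co <- generate_cohort(cfg, n_labeled = 5, m_unlabeled = 10, n_val = 5,
                        n_test = 10, domain = "target", seed = 2)
  expect_length(co$cases, 30)
  expect_length(cohort_cases(co, "train", labeled = TRUE), 5)
  expect_length(cohort_cases(co, "train", labeled = FALSE), 10)
  expect_length(cohort_cases(co, "val"), 5)
  expect_length(cohort_cases(co, "test"), 10)
  expect_true(all(vapply(cohort_cases(co, "train", labeled = FALSE),
                         function(cs) is.null(cs$labels), TRUE)))
  expect_false(anyDuplicated(co$manifest$case_id) > 0)

  empty <- generate_cohort(cfg, n_labeled = 2, m_unlabeled = 0, n_val = 1,
                           n_test = 0, seed = 3)
  expect_length(cohort_cases(empty, "train", labeled = FALSE), 0)

  co2 <- generate_cohort(cfg, n_labeled = 5, m_unlabeled = 10, n_val = 5,
                         n_test = 10, domain = "target", seed = 99)
  expect_identical(co$manifest$split, co2$manifest$split)
  expect_identical(co$manifest$labeled, co2$manifest$labeled)
  expect_false(identical(co$cases[[1]]$volume$data, co2$cases[[1]]$volume$data))
})

test_that("cohorts round-trip through NIfTI files and a manifest CSV", {
  cfg <- tiny_phantom_config()
  co <- generate_cohort(cfg, n_labeled = 2, m_unlabeled = 1, n_val = 1,
                        n_test = 1, seed = 4)
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(man$image_path)))
  back <- read_cohort(dir)
  expect_identical(names(back$cases), names(co$cases))
  expect_equal(back$cases[[1]]$volume$data, co$cases[[1]]$volume$data)
  expect_identical(back$cases[[1]]$labels$data, co$cases[[1]]$labels$data)
  unl <- cohort_cases(back, "train", labeled = FALSE)[[1]]
  expect_null(unl$labels)
})
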