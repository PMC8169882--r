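test_that("thresholding assigns the argmax exceeder or leaves voxels unlabeled", {
  p <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.4, 0.3, 0.2, 0.1), 4)
  mu <- prob_map(p, c(2, 1, 1))
  t05 <- threshold_labels(mu, 0.5)
  expect_identical(as.integer(t05$data), c(0L, UNLABELED))
  # lower threshold: argmax among the exceeders
  t02 <- threshold_labels(mu, 0.2)
  expect_identical(as.integer(t02$data)[2], 0L)
  expect_error(threshold_labels(mu, 1.2), class = "segda_usage_error")
})

test_that("largest-component filtering matches a flood-fill oracle", {
  # deterministic toy: two components of size 10 and 3
  m <- array(0L, c(8, 8, 4))
  m[2:6, 2, 1] <- 1L; m[2:6, 3, 1] <- 1L   # size 10
  m[8, 8, 4] <- 1L; m[8, 7, 4] <- 1L; m[7, 8, 4] <- 1L  # size 3
  kept <- keep_largest_component(m, 26)
  expect_identical(sum(kept), 10L)
  expect_true(all(kept[2:6, 2:3, 1] == 1L))
  # identity on a single component; empty stays empty
  single <- array(0L, c(4, 4, 2)); single[2:3, 2:3, 1] <- 1L
  expect_identical(keep_largest_component(single), single)
  expect_identical(keep_largest_component(array(0L, c(4, 4, 2))),
                   array(0L, c(4, 4, 2)))
})

test_that("component labelling agrees with an independent oracle across connectivities", {
  set.seed(42)
  for (i in 1:20) {
    m <- array(as.integer(runif(8 * 8 * 4) < 0.35), c(8, 8, 4))
    for (conn in c(6, 26)) {
      ours <- keep_largest_component(m, conn)
      lab <- oracle_components(m, conn)
      sizes <- tabulate(lab)
      if (length(sizes) == 0) {
        expect_identical(sum(ours), 0L)
      } else {
        expect_identical(sum(ours), max(sizes))
        # kept voxels form exactly one oracle component
        expect_length(unique(lab[ours == 1L]), 1L)
      }
    }
  }
})

test_that("post-processing exempts the paired-tube class and unlabels removed satellites", {
  # class 3 (lateral-tube analog): two fragments, both retained
  d <- c(8, 8, 4)
  base <- matrix(0.1, 4, prod(d))
  base[1, ] <- 0.7
  arr_idx <- function(x, y, z) x + 8 * (y - 1) + 64 * (z - 1)
  frag <- c(arr_idx(2, 2, 1), arr_idx(6, 6, 3))
  base[, frag] <- c(0.1, 0.05, 0.05, 0.8)
  # class 1 (blob analog): a main component and a satellite voxel
  main <- c(arr_idx(4, 4, 2), arr_idx(5, 4, 2), arr_idx(4, 5, 2))
  sat <- arr_idx(8, 1, 4)
  base[, c(main, sat)] <- c(0.1, 0.8, 0.05, 0.05)
  mu <- prob_map(sweep(base, 2, colSums(base), "/"), d)
  out <- postprocess_prediction(mu, postprocess_policy(threshold = 0.5))
  expect_identical(as.integer(out$data[2, 2, 1]), 3L)
  expect_identical(as.integer(out$data[6, 6, 3]), 3L)
  expect_identical(as.integer(out$data[4, 4, 2]), 1L)
  expect_identical(as.integer(out$data[8, 1, 4]), UNLABELED)
})

test_that("post-processing never adds labeled voxels and never filters background", {
  for (s in 1:5) {
    mu <- random_probmap(c(8, 8, 4), seed = s)
    thr <- threshold_labels(mu, 0.4)
    out <- postprocess_prediction(mu, postprocess_policy(threshold = 0.4))
    labeled_thr <- thr$data != UNLABELED
    labeled_out <- out$data != UNLABELED
    expect_true(all(labeled_thr[labeled_out]))
    # background voxels of the thresholded map are untouched
    bg <- thr$data == 0L
    expect_true(all(out$data[bg] == 0L))
  }
})

test_that("confident single-component predictions pass through unchanged", {
  cs <- tiny_case(seed = 6, grid = c(24, 24, 8))
  p <- one_hot(cs$labels) * 0.94 + 0.02
  mu <- prob_map(p, dim(cs$labels$data), cs$labels$spacing)
  thr <- threshold_labels(mu, 0.5)
  out <- postprocess_prediction(mu, postprocess_policy())
  expect_identical(out$data, thr$data)
})

test_that("policy validation rejects overlapping class sets", {
  expect_error(postprocess_policy(cc_filtered_classes = c(1, 3),
                                  cc_exempt_classes = 3),
               class = "segda_usage_error")
  expect_error(postprocess_policy(connectivity = 10),
               class = "segda_usage_error")
})
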