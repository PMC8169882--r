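test_that("voxel entropy hits the closed-form values", {
  p <- matrix(c(0.25, 0.25, 0.25, 0.25,   # uniform -> ln 4
                1, 0, 0, 0,               # one-hot -> 0
                0.5, 0.5, 0, 0),          # binary symmetric -> ln 2
              nrow = 4)
  mu <- prob_map(p, c(3, 1, 1))
  H <- voxel_entropy(mu)
  expect_equal(as.numeric(H), c(log(4), 0, log(2)))
  expect_error(voxel_entropy(prob_map(p * NA, c(3, 1, 1))))
})

test_that("entropy is bounded by [0, ln C] for random probability maps", {
  for (s in 1:10) {
    mu <- random_probmap(c(4, 4, 2), seed = s)
    H <- voxel_entropy(mu)
    expect_true(all(H >= 0 & H <= log(4) + 1e-12))
  }
})

test_that("case entropy is the mean voxel entropy", {
  p <- cbind(matrix(rep(c(0.5, 0.5, 0, 0), 8), 4),   # ln 2 at half the voxels
             matrix(rep(c(1, 0, 0, 0), 8), 4))       # 0 at the other half
  mu <- prob_map(p, c(4, 4, 1))
  expect_equal(case_entropy(mu), log(2) / 2)
  one <- prob_map(matrix(rep(c(0, 1, 0, 0), 4), 4), c(2, 2, 1))
  expect_equal(case_entropy(one), 0)
})

test_that("entropy weights follow the max-normalization formulas", {
  expect_equal(entropy_weights(c(0.2, 0.4)), c(0.5, 0))
  # all equal and > 0 -> all weights 0
  expect_equal(entropy_weights(c(0.3, 0.3, 0.3)), c(0, 0, 0))
  # all-zero degenerate -> full confidence convention
  expect_equal(entropy_weights(c(0, 0)), c(1, 1))
  w <- entropy_weights(c(0.1, 0.7, 0.4))
  expect_true(all(w >= 0 & w <= 1))
  expect_true(any(w == 0))
  expect_error(entropy_weights(c(-0.1, 0.2)), class = "segda_usage_error")
})

test_that("weights are invariant to the entropy logarithm base", {
  h_nats <- c(0.13, 0.52, 0.31, 0.02)
  h_bits <- h_nats / log(2)
  expect_equal(entropy_weights(h_nats), entropy_weights(h_bits))
})

test_that("ensemble mean is idempotent, permutation-invariant and normalized", {
  vol <- volume(array(rnorm(8 * 8 * 2), c(8, 8, 2)))
  m1 <- build_model(tiny_spec(), seed = 1)
  m2 <- build_model(tiny_spec(), seed = 2)
  m3 <- build_model(tiny_spec(), seed = 3)
  same <- as_ensemble(list(m1, m1, m1))
  expect_equal(ensemble_mean(same, vol)$probs, predict_volume(m1, vol)$probs)
  e123 <- ensemble_mean(as_ensemble(list(m1, m2, m3)), vol)
  e312 <- ensemble_mean(as_ensemble(list(m3, m1, m2)), vol)
  expect_equal(e123$probs, e312$probs)
  expect_lt(max(abs(colSums(e123$probs) - 1)), 1e-5)
  # singleton ensemble mean equals the member output
  expect_equal(ensemble_mean(as_ensemble(list(m2)), vol)$probs,
               predict_volume(m2, vol)$probs)
})

test_that("majority voting follows unanimity, majority and the tie rule", {
  onehot_map <- function(cls) {
    p <- matrix(1e-9, 4, 2)
    p[cbind(cls + 1, 1:2)] <- 1 - 3e-9
    prob_map(sweep(p, 2, colSums(p), "/"), c(2, 1, 1))
  }
  # unanimity
  un <- segda:::majority_from_predictions(list(onehot_map(c(2, 1)),
                                               onehot_map(c(2, 1)),
                                               onehot_map(c(2, 1))))
  expect_identical(as.integer(un$data), c(2L, 1L))
  # 3-of-5 simple majority
  mj <- segda:::majority_from_predictions(list(onehot_map(c(1, 0)),
                                               onehot_map(c(1, 0)),
                                               onehot_map(c(1, 3)),
                                               onehot_map(c(2, 3)),
                                               onehot_map(c(2, 3))))
  expect_identical(as.integer(mj$data)[1], 1L)
  # 2-2 tie broken by the higher ensemble-mean probability
  soft <- function(a, b) {
    p <- matrix(0.05, 4, 1); p[a + 1, 1] <- b
    prob_map(sweep(p, 2, colSums(p), "/"), c(1, 1, 1))
  }
  tie <- segda:::majority_from_predictions(list(soft(0, 0.70), soft(0, 0.70),
                                                soft(1, 0.60), soft(1, 0.60)))
  expect_identical(as.integer(tie$data), 0L)
  # identical members vote the member argmax everywhere
  mu <- random_probmap(c(4, 4, 2), seed = 8)
  same <- segda:::majority_from_predictions(list(mu, mu, mu))
  expect_identical(as.integer(same$data),
                   max.col(t(mu$probs), ties.method = "first") - 1L)
})

test_that("training an ensemble produces distinct members controlled by seeds", {
  cases <- lapply(1:3, tiny_case)
  cfg <- train_config(learning_rate = 1e-2, max_epochs = 2, batch_size = 2,
                      patience = 2, seed = 1, augment_flip = FALSE)
  ens <- train_ensemble(tiny_spec(), cases[1:2], cases[3], k = 2,
                        seeds = c(4, 5), config = cfg)
  expect_s3_class(ens, "segda_ensemble")
  expect_length(ens$members, 2)
  expect_false(identical(ens$members[[1]]$params, ens$members[[2]]$params))
  expect_warning(
    train_ensemble(tiny_spec(), cases[1:2], cases[3], k = 2,
                   seeds = c(4, 4), config = cfg),
    "duplicate"
  )
})
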