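test_that("the full-size network has exactly 3,197,028 trainable parameters", {
  m <- build_model(model_spec(), seed = 1)
  expect_identical(count_parameters(m), 3197028L)
})

test_that("parameter groups are disjoint and partition all parameters", {
  for (spec in list(model_spec(), reduced_spec(), tiny_spec())) {
    m <- build_model(spec, seed = 2)
    g <- parameter_groups(m)
    expect_length(intersect(g$encoder, g$bottleneck), 0)
    expect_length(intersect(g$encoder, g$decoder), 0)
    expect_length(intersect(g$bottleneck, g$decoder), 0)
    expect_setequal(c(g$encoder, g$bottleneck, g$decoder), names(m$params))
    expect_identical(sum(group_parameter_counts(m)), count_parameters(m))
    expect_true(all(c("out_conv_w", "out_conv_b") %in% g$decoder))
  }
})

test_that("weight initialization is deterministic in the seed", {
  a <- build_model(tiny_spec(), seed = 7)
  b <- build_model(tiny_spec(), seed = 7)
  expect_identical(a$params, b$params)
  c2 <- build_model(tiny_spec(), seed = 8)
  expect_false(identical(a$params, c2$params))
})

test_that("forward pass preserves spatial dims and produces softmax output", {
  m <- build_model(reduced_spec(), seed = 1)
  vol <- volume(array(rnorm(16 * 16 * 4), c(16, 16, 4)), spacing = c(1, 1, 3))
  mu <- predict_volume(m, vol)
  expect_identical(mu$dim, c(16L, 16L, 4L))
  expect_identical(mu$n_classes, 4L)
  expect_true(all(mu$probs >= 0 & mu$probs <= 1))
  expect_lt(max(abs(colSums(mu$probs) - 1)), 1e-5)
  # deterministic inference
  mu2 <- predict_volume(m, vol)
  expect_identical(mu$probs, mu2$probs)
})

test_that("softmax normalization holds for random weights and inputs", {
  for (s in 1:3) {
    m <- build_model(tiny_spec(), seed = s)
    vol <- volume(array(rnorm(8 * 8 * 2, sd = s), c(8, 8, 2)))
    mu <- predict_volume(m, vol)
    expect_lt(max(abs(colSums(mu$probs) - 1)), 1e-5)
  }
})

test_that("pooling-incompatible input dims raise an explanatory shape error", {
  m <- build_model(reduced_spec(), seed = 1)
  vol <- volume(array(0, c(15, 16, 4)))
  expect_error(predict_volume(m, vol), "divisible",
               class = "segda_shape_error")
})

test_that("an overfit toy model memorizes its training case", {
  cs <- tiny_case(seed = 30)
  m <- build_model(tiny_spec(), seed = 1)
  tc <- train_config(learning_rate = 1e-2, max_epochs = 60, batch_size = 1,
                     patience = 60, seed = 1, augment_flip = FALSE)
  tm <- train_model(m, list(cs), list(cs), tc)
  pred <- argmax_labels(predict_volume(tm, cs$volume))
  agreement <- mean(pred$data == cs$labels$data)
  expect_gt(agreement, 0.97)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(99)
  m <- build_model(tiny_spec(), seed = 5)
  dims <- c(8L, 8L, 2L)
  x <- matrix(rnorm(prod(dims)), nrow = 1)
  Y <- random_onehot(dims, seed = 1)
  M <- as.numeric(runif(prod(dims)) < 0.8)
  fw <- segda:::nn_forward(m, x, dims, keep_cache = TRUE)
  lg <- segda:::partial_dice_with_grad(fw$probs, Y, M, 0.7)
  g <- segda:::nn_backward(m, fw, lg$dP)
  lossfun <- function(model) {
    f <- segda:::nn_forward(model, x, dims, keep_cache = FALSE)
    segda:::partial_dice_terms(f$probs, Y, M, 0.7, 1e-5)$loss
  }
  eps <- 1e-6
  for (nm in c("enc1_conv1_w", "enc3_conv2_ng", "dec1_conv2_w", "out_conv_b")) {
    i <- sample(length(m$params[[nm]]), 1)
    up <- m; up$params[[nm]][i] <- up$params[[nm]][i] + eps
    dn <- m; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
    num <- (lossfun(up) - lossfun(dn)) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-3)
  }
})

test_that("checkpoints are self-describing and restore weights exactly", {
  m <- build_model(tiny_spec(), seed = 13)
  m$params$enc1_conv1_w[] <- rnorm(length(m$params$enc1_conv1_w))
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, path)
  r <- load_model(path)
  expect_equal(r$spec, m$spec)
  expect_equal(r$params, m$params)
})
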