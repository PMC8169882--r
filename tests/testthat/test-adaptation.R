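adapt_fixture <- function() {
  cfg <- tiny_phantom_config()
  list(
    labeled = lapply(1:2, function(s) tiny_case(seed = 50 + s)),
    unlabeled = lapply(1:3, function(s) {
      cs <- tiny_case(seed = 60 + s, domain = "target")
      list(case_id = cs$case_id, volume = cs$volume, labels = NULL,
           gt = cs$labels)
    }),
    val = lapply(1:2, function(s) tiny_case(seed = 70 + s))
  )
}

fast_adapt_config <- function(...) {
  args <- list(
    tl_learning_rate = 3e-3, tl_max_epochs = 3, tl_patience = 3,
    sl_learning_rate = 1e-3, sl_max_epochs = 2, sl_patience = 2,
    sl_max_iters = 2,
    scratch_config = train_config(learning_rate = 1e-2, max_epochs = 3,
                                  batch_size = 2, patience = 3, seed = 1)
  )
  args[names(list(...))] <- list(...)
  do.call(adaptation_config, args)
}

test_that("transfer learning freezes the decoder bit-exactly", {
  fx <- adapt_fixture()
  src <- build_model(tiny_spec(), seed = 21)
  tl <- transfer_learn(src, fx$labeled, fx$val, fast_adapt_config())
  g <- parameter_groups(src)
  for (nm in g$decoder) expect_identical(tl$params[[nm]], src$params[[nm]])
  enc_changed <- vapply(c(g$encoder, g$bottleneck),
                        function(nm) !identical(tl$params[[nm]], src$params[[nm]]),
                        TRUE)
  expect_true(any(enc_changed))
})

test_that("transfer learning with a zero epoch budget is a no-op", {
  fx <- adapt_fixture()
  src <- build_model(tiny_spec(), seed = 22)
  out <- transfer_learn(src, fx$labeled, fx$val,
                        fast_adapt_config(tl_max_epochs = 0))
  expect_identical(out$params, src$params)
  expect_error(transfer_learn(src, list(), fx$val, fast_adapt_config()),
               class = "segda_usage_error")
})

test_that("pseudo-labels carry consistent masks and configured weights", {
  fx <- adapt_fixture()
  ens <- as_ensemble(list(build_model(tiny_spec(), 1),
                          build_model(tiny_spec(), 2)))
  ps <- generate_pseudo_labels(ens, fx$unlabeled, postprocess_policy(),
                               weight_mode = "fixed")
  expect_length(ps, 3)
  for (p in ps) {
    expect_equal(p$weight, 0.5)
    expect_identical(p$mask, label_mask(p$labels))
  }
  pe <- generate_pseudo_labels(ens, fx$unlabeled, postprocess_policy(),
                               weight_mode = "entropy")
  w <- vapply(pe, `[[`, 0, "weight")
  expect_true(all(w >= 0 & w <= 1))
  ents <- vapply(pe, `[[`, 0, "entropy")
  expect_equal(w, entropy_weights(ents))
  expect_length(generate_pseudo_labels(ens, list(), postprocess_policy()), 0)
  # single-case entropy degenerate falls back to the fixed weight
  expect_warning(
    one <- generate_pseudo_labels(ens, fx$unlabeled[1], postprocess_policy(),
                                  weight_mode = "entropy"),
    "degenerate"
  )
  expect_equal(one[[1]]$weight, 0.5)
})

test_that("self-learning regenerates pseudo-labels each cycle and respects the cap", {
  fx <- adapt_fixture()
  src <- as_ensemble(list(build_model(tiny_spec(), 31)))
  cfg <- fast_adapt_config(pseudo_weight_mode = "fixed")
  out <- self_learning(src, fx$labeled, fx$unlabeled, fx$val, cfg)
  expect_s3_class(out, "segda_ensemble")
  rep <- out$sl_report
  expect_lte(max(rep$iteration), cfg$sl_max_iters)
  # monotone selection: returned models' val DSC >= input models' val DSC
  expect_gte(max(rep$val_dsc, na.rm = TRUE) + 1e-12, rep$val_dsc[1])
  in_dsc <- segda:::evaluate_ensemble_dsc(src, fx$val, cfg$policy)
  out_dsc <- segda:::evaluate_ensemble_dsc(out, fx$val, cfg$policy)
  expect_gte(out_dsc + 1e-12, in_dsc)
})

test_that("an empty pseudo pool degenerates to supervised fine-tuning with a warning", {
  fx <- adapt_fixture()
  src <- as_ensemble(list(build_model(tiny_spec(), 33)))
  expect_warning(
    out <- self_learning(src, fx$labeled, list(), fx$val,
                         fast_adapt_config(sl_max_iters = 1)),
    "degenerates"
  )
  expect_s3_class(out, "segda_ensemble")
})

test_that("the identity pipeline returns the source models unchanged", {
  cfg <- tiny_phantom_config()
  cohort <- generate_cohort(cfg, n_labeled = 2, m_unlabeled = 2, n_val = 1,
                            n_test = 1, domain = "target", seed = 77)
  src <- as_ensemble(list(build_model(tiny_spec(), 41),
                          build_model(tiny_spec(), 42)))
  res <- run_domain_adaptation(src, cohort,
                               fast_adapt_config(use_transfer = FALSE,
                                                 use_selflearn = FALSE))
  expect_identical(res$ensemble$members[[1]]$params, src$members[[1]]$params)
  expect_identical(res$ensemble$members[[2]]$params, src$members[[2]]$params)
  expect_length(res$report$stages, 0)
})

test_that("the full pipeline reports its stages in order", {
  cfg <- tiny_phantom_config()
  cohort <- generate_cohort(cfg, n_labeled = 2, m_unlabeled = 2, n_val = 1,
                            n_test = 1, domain = "target", seed = 78)
  src <- as_ensemble(list(build_model(tiny_spec(), 43)))
  res <- run_domain_adaptation(src, cohort, fast_adapt_config(sl_max_iters = 1))
  expect_identical(res$report$stages, c("transfer", "self-learning"))
  expect_true(is.finite(res$report$val_dsc))
  no_lab <- generate_cohort(cfg, n_labeled = 0, m_unlabeled = 2, n_val = 1,
                            n_test = 0, domain = "target", seed = 79)
  expect_error(run_domain_adaptation(src, no_lab, fast_adapt_config()),
               class = "segda_usage_error")
})

test_that("ablation arm configurations map to the documented switches", {
  base <- fast_adapt_config()
  expect_false(arm_config("source-only", base)$use_transfer)
  expect_false(arm_config("source-only", base)$use_selflearn)
  expect_identical(arm_config("scratch", base)$init, "scratch")
  tl <- arm_config("tl", base)
  expect_true(tl$use_transfer && !tl$use_selflearn && !tl$use_ensemble)
  tlsl <- arm_config("tl-sl", base)
  expect_true(tlsl$use_selflearn && !tlsl$use_ensemble)
  expect_identical(tlsl$pseudo_weight_mode, "fixed")
  ensh <- arm_config("ens-h", base)
  expect_true(!ensh$use_transfer && ensh$use_selflearn && ensh$use_ensemble)
  expect_identical(ensh$pseudo_weight_mode, "entropy")
  full <- arm_config("tl-ens-h", base)
  expect_true(full$use_transfer && full$use_selflearn && full$use_ensemble)
  expect_identical(full$pseudo_weight_mode, "entropy")
})

test_that("tidiers summarize models, ensembles and metrics", {
  m <- build_model(tiny_spec(), 1)
  td <- tidy(m)
  expect_identical(sum(td$n_params), count_parameters(m))
  expect_setequal(unique(td$group), c("encoder", "bottleneck", "decoder"))
  g <- glance(m)
  expect_identical(g$n_params, count_parameters(m))
  ens <- as_ensemble(list(m, build_model(tiny_spec(), 2)))
  expect_identical(nrow(tidy(ens)), 2L)
  expect_identical(glance(ens)$k, 2L)
})
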