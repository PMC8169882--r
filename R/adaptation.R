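#' Configuration of the two-stage domain adaptation
#'
#' Stage I (transfer learning) fine-tunes the encoder and bottleneck of a
#' source-trained model on the few labeled target cases with a reduced
#' learning rate (1e-4) while the decoder stays frozen; stage II
#' (self-learning) alternates pseudo-label generation on the unlabeled
#' target cases with retraining of all weights under the partial Dice
#' loss, for at most `sl_max_iters` cycles (three to five are typical) or
#' until the validation metric stops improving.  Pseudo-label cases enter
#' the loss either with the fixed weight 0.5 or with the entropy-derived
#' weight `1 - H_i / max_j H_j`; ground-truth cases always carry weight 1.
#'
#' @param tl_learning_rate stage-I learning rate.
#' @param tl_max_epochs,tl_patience stage-I epoch budget and early-stop
#'   patience (30 epochs of patience at full scale).
#' @param sl_learning_rate stage-II learning rate; defaults to the stage-I
#'   rate (retraining continues from the current weights, so the
#'   fine-tuning rate is kept).
#' @param sl_max_epochs,sl_patience per-retraining epoch budget/patience.
#' @param sl_max_iters,sl_min_iters bounds on self-learning cycles.
#' @param pseudo_weight_mode `"entropy"` or `"fixed"`.
#' @param fixed_weight pseudo-label weight in fixed mode (0.5).
#' @param use_transfer,use_selflearn,use_ensemble ablation switches.
#' @param init `"source"` (start from the source models) or `"scratch"`
#'   (random initialization trained on the labeled target cases only).
#' @param policy a [postprocess_policy()] for pseudo-label generation and
#'   evaluation.
#' @param scratch_config a [train_config()] used for the from-scratch arm.
#' @param batch_size,augment_flip,val_metric shared training options.
#' @param seed base seed for stage-II retraining shuffles.
#' @return an object of class `segda_adaptation_config`.
#' @export
adaptation_config <- function(tl_learning_rate = 1e-4,
                              tl_max_epochs = 300L, tl_patience = 30L,
                              sl_learning_rate = NULL,
                              sl_max_epochs = NULL, sl_patience = NULL,
                              sl_max_iters = 5L, sl_min_iters = 1L,
                              pseudo_weight_mode = c("entropy", "fixed"),
                              fixed_weight = 0.5,
                              use_transfer = TRUE, use_selflearn = TRUE,
                              use_ensemble = TRUE,
                              init = c("source", "scratch"),
                              policy = postprocess_policy(),
                              scratch_config = train_config(),
                              batch_size = 2L, augment_flip = TRUE,
                              val_metric = "dsc", seed = 1L) {
  if (tl_learning_rate <= 0) {
    abort("learning rates must be > 0.", class = "segda_usage_error")
  }
  if (sl_max_iters < 1) {
    abort("`sl_max_iters` must be >= 1.", class = "segda_usage_error")
  }
  structure(
    list(tl_learning_rate = tl_learning_rate,
         tl_max_epochs = as.integer(tl_max_epochs),
         tl_patience = as.integer(tl_patience),
         sl_learning_rate = sl_learning_rate %||% tl_learning_rate,
         sl_max_epochs = as.integer(sl_max_epochs %||% tl_max_epochs),
         sl_patience = as.integer(sl_patience %||% tl_patience),
         sl_max_iters = as.integer(sl_max_iters),
         sl_min_iters = as.integer(sl_min_iters),
         pseudo_weight_mode = match.arg(pseudo_weight_mode),
         fixed_weight = fixed_weight,
         use_transfer = isTRUE(use_transfer),
         use_selflearn = isTRUE(use_selflearn),
         use_ensemble = isTRUE(use_ensemble),
         init = match.arg(init),
         policy = policy,
         scratch_config = scratch_config,
         batch_size = as.integer(batch_size),
         augment_flip = isTRUE(augment_flip),
         val_metric = val_metric,
         seed = as.integer(seed)),
    class = "segda_adaptation_config"
  )
}

#' Stage I: decoder-frozen transfer learning
#'
#' Fine-tunes a source model on the labeled target cases, updating only
#' the encoder and bottleneck parameter groups; every decoder parameter
#' (including the final classification layer) is returned bit-identical.
#' The snapshot with the best validation performance is returned.  With
#' `tl_max_epochs = 0` the source model is returned unchanged.
#'
#' @param source_model a `segda_model` trained in the source domain.
#' @param labeled_target_train,labeled_target_val labeled target case lists.
#' @param config an [adaptation_config()].
#' @return the fine-tuned `segda_model`.
#' @export
transfer_learn <- function(source_model, labeled_target_train,
                           labeled_target_val,
                           config = adaptation_config()) {
  if (length(labeled_target_train) == 0) {
    abort("transfer learning needs at least one labeled target case.",
          class = "segda_usage_error")
  }
  if (config$tl_max_epochs == 0L) return(source_model)
  tc <- train_config(
    learning_rate = config$tl_learning_rate,
    max_epochs = config$tl_max_epochs,
    batch_size = config$batch_size,
    patience = min(config$tl_patience, config$tl_max_epochs),
    trainable_groups = c("encoder", "bottleneck"),
    loss = "dice",
    seed = source_model$seed,
    augment_flip = config$augment_flip,
    val_metric = config$val_metric
  )
  train_model(source_model, labeled_target_train, labeled_target_val, tc)
}

#' Generate pseudo-labels for unlabeled cases
#'
#' Predicts each case with the ensemble mean (or a single model),
#' post-processes the probabilities into labels with explicit unlabeled
#' voxels, and attaches the voxel mask and a per-case sample weight: the
#' fixed 0.5 in fixed mode, or `1 - H_i / max_j H_j` from the case
#' entropies in entropy mode (weights are recomputed over the current pool
#' at every self-learning cycle).  With a single unlabeled case the
#' entropy normalization degenerates (its own maximum would force weight
#' 0, silencing all pseudo supervision), so the fixed weight is used with
#' a warning.
#'
#' @param models a `segda_ensemble` or single `segda_model`.
#' @param unlabeled_cases list of case records (with `volume`).
#' @param policy a [postprocess_policy()].
#' @param weight_mode `"entropy"` or `"fixed"`.
#' @param fixed_weight weight used in fixed mode (and in the single-case
#'   entropy degenerate).
#' @return list of pseudo-label records: `case_id`, `volume`, `labels`,
#'   `mask`, `weight`, `entropy`; empty input gives an empty list.
#' @export
generate_pseudo_labels <- function(models, unlabeled_cases,
                                   policy = postprocess_policy(),
                                   weight_mode = c("entropy", "fixed"),
                                   fixed_weight = 0.5) {
  weight_mode <- match.arg(weight_mode)
  if (length(unlabeled_cases) == 0) return(list())
  if (inherits(models, "segda_model")) models <- as_ensemble(list(models))
  recs <- lapply(unlabeled_cases, function(cs) {
    mu <- ensemble_mean(models, cs$volume)
    labels <- postprocess_prediction(mu, policy)
    list(case_id = cs$case_id %||% NA_character_,
         volume = cs$volume,
         labels = labels,
         mask = label_mask(labels),
         entropy = case_entropy(mu))
  })
  ents <- vapply(recs, `[[`, 0, "entropy")
  weights <- if (weight_mode == "fixed") {
    rep(fixed_weight, length(recs))
  } else if (length(recs) == 1L && ents[1] > 0) {
    warn("single unlabeled case: entropy normalization is degenerate, using the fixed pseudo-label weight.")
    fixed_weight
  } else {
    entropy_weights(ents)
  }
  purrr::map2(recs, weights, function(r, w) {
    r$weight <- w
    r
  })
}

# Mean foreground DSC of the postprocessed ensemble-mean prediction.
evaluate_ensemble_dsc <- function(ensemble, cases, policy) {
  if (length(cases) == 0) return(NA_real_)
  vals <- vapply(cases, function(cs) {
    pred <- predict_labels(ensemble, cs$volume, vote = "mean", policy = policy)
    m <- evaluate_case(pred, cs$labels)
    mean(m$dsc[m$gt_present])
  }, 0)
  mean(vals)
}

#' Predict a label map with an ensemble (or model)
#'
#' `vote = "mean"` post-processes the ensemble-mean probabilities;
#' `vote = "majority"` takes the member majority vote.  With
#' `policy = NULL` the mean route uses a plain argmax (no thresholding or
#' component filtering).
#'
#' @param models a `segda_ensemble` or `segda_model`.
#' @param vol a [volume()].
#' @param vote `"mean"` or `"majority"`.
#' @param policy a [postprocess_policy()] or `NULL`.
#' @return a [label_map()].
#' @export
predict_labels <- function(models, vol, vote = c("mean", "majority"),
                           policy = postprocess_policy()) {
  vote <- match.arg(vote)
  if (inherits(models, "segda_model")) models <- as_ensemble(list(models))
  if (vote == "majority") return(majority_vote(models, vol))
  mu <- ensemble_mean(models, vol)
  if (is.null(policy)) argmax_labels(mu) else postprocess_prediction(mu, policy)
}

#' Stage II: uncertainty-guided self-learning
#'
#' Cycles of label propagation and retraining: at each iteration the
#' current ensemble generates pseudo-labels for the unlabeled pool
#' ([generate_pseudo_labels()]), then every member is retrained from its
#' current weights on the labeled cases (weight 1) plus the pseudo-labeled
#' cases (their per-case weights) under the partial Dice loss with all
#' parameter groups trainable.  The cycle stops when the validation metric
#' fails to improve (after at least `sl_min_iters` iterations) or at
#' `sl_max_iters`; the models of the best-validation iteration (including
#' the input models as iteration 0) are returned.
#'
#' @param models a `segda_ensemble` or single `segda_model` (typically the
#'   stage-I output).
#' @param labeled_cases labeled target training cases.
#' @param unlabeled_cases unlabeled target cases (pseudo-label pool); with
#'   an empty pool the stage degenerates to supervised fine-tuning with a
#'   warning.
#' @param val_cases labeled validation cases.
#' @param config an [adaptation_config()].
#' @param oracle_labels optional named list of ground-truth [label_map()]s
#'   for the unlabeled cases; when supplied they are used verbatim as
#'   pseudo-labels with weight 1 (a diagnostic upper bound: self-learning
#'   then reduces to supervised training on the union set).
#' @return a `segda_ensemble` with an `sl_report` tibble attached
#'   (iteration, validation DSC, pseudo-label statistics).
#' @export
self_learning <- function(models, labeled_cases, unlabeled_cases, val_cases,
                          config = adaptation_config(),
                          oracle_labels = NULL) {
  if (length(labeled_cases) == 0) {
    abort("self-learning needs at least one labeled case.",
          class = "segda_usage_error")
  }
  if (inherits(models, "segda_model")) models <- as_ensemble(list(models))
  if (length(unlabeled_cases) == 0 && is.null(oracle_labels)) {
    warn("empty pseudo-label pool: self-learning degenerates to supervised fine-tuning.")
  }
  labeled_recs <- lapply(labeled_cases, function(cs) {
    list(case_id = cs$case_id, volume = cs$volume, labels = cs$labels,
         mask = NULL, weight = 1)
  })
  best <- models
  best_dsc <- evaluate_ensemble_dsc(models, val_cases, config$policy)
  report <- list(tibble(iteration = 0L, val_dsc = best_dsc,
                        mean_pseudo_weight = NA_real_,
                        mean_labeled_fraction = NA_real_))
  for (it in seq_len(config$sl_max_iters)) {
    pseudo <- if (!is.null(oracle_labels)) {
      lapply(unlabeled_cases, function(cs) {
        list(case_id = cs$case_id, volume = cs$volume,
             labels = oracle_labels[[cs$case_id]],
             mask = label_mask(oracle_labels[[cs$case_id]]),
             weight = 1, entropy = 0)
      })
    } else {
      generate_pseudo_labels(models, unlabeled_cases, config$policy,
                             config$pseudo_weight_mode, config$fixed_weight)
    }
    train_set <- c(labeled_recs, pseudo)
    members <- vector("list", length(models$members))
    for (m in seq_along(models$members)) {
      tc <- train_config(
        learning_rate = config$sl_learning_rate,
        max_epochs = config$sl_max_epochs,
        batch_size = config$batch_size,
        patience = min(config$sl_patience, max(1L, config$sl_max_epochs)),
        trainable_groups = c("encoder", "bottleneck", "decoder"),
        loss = "partial_dice",
        seed = (models$seeds[m] + 7919L * it) %% .Machine$integer.max,
        augment_flip = config$augment_flip,
        val_metric = config$val_metric
      )
      members[[m]] <- train_model(models$members[[m]], train_set, val_cases, tc)
    }
    models <- new_ensemble(members, models$seeds)
    vd <- evaluate_ensemble_dsc(models, val_cases, config$policy)
    report[[it + 1L]] <- tibble(
      iteration = it, val_dsc = vd,
      mean_pseudo_weight = if (length(pseudo)) {
        mean(vapply(pseudo, `[[`, 0, "weight"))
      } else NA_real_,
      mean_labeled_fraction = if (length(pseudo)) {
        mean(vapply(pseudo, function(p) mean(p$mask), 0))
      } else NA_real_)
    improved <- !is.na(vd) && (is.na(best_dsc) || vd > best_dsc + 1e-12)
    if (improved) {
      best <- models
      best_dsc <- vd
    } else if (it >= config$sl_min_iters) {
      break
    }
  }
  best$sl_report <- dplyr::bind_rows(report)
  best
}

#' Run the full domain adaptation pipeline
#'
#' Applies, according to the configuration flags, stage-I transfer
#' learning to every member and stage-II self-learning jointly, starting
#' from the source models (or from random initializations trained on the
#' labeled target cases for the from-scratch arm).  With both stages
#' disabled the source models are returned unchanged (the source-only
#' baseline).
#'
#' @param source_models a `segda_ensemble`, list of models, or single
#'   `segda_model` trained in the source domain.
#' @param target_cohort a `segda_cohort` with labeled train/val cases and
#'   optionally unlabeled train cases.
#' @param config an [adaptation_config()].
#' @return `list(ensemble, report)`: the adapted ensemble and a report
#'   with the stages executed, per-split mean foreground DSC and the
#'   configuration.
#' @export
run_domain_adaptation <- function(source_models, target_cohort,
                                  config = adaptation_config()) {
  if (inherits(source_models, "segda_model")) {
    source_models <- as_ensemble(list(source_models))
  } else if (is.list(source_models) && !inherits(source_models, "segda_ensemble")) {
    source_models <- as_ensemble(source_models)
  }
  labeled <- cohort_cases(target_cohort, "train", labeled = TRUE)
  unlabeled <- cohort_cases(target_cohort, "train", labeled = FALSE)
  val <- cohort_cases(target_cohort, "val")
  test <- cohort_cases(target_cohort, "test")
  if (length(labeled) == 0) {
    abort("the target cohort has no labeled training cases.",
          class = "segda_usage_error")
  }
  if (!config$use_ensemble) {
    source_models <- new_ensemble(source_models$members[1],
                                  source_models$seeds[1])
  }
  stages <- character(0)
  models <- source_models
  if (config$init == "scratch") {
    members <- lapply(seq_along(models$members), function(i) {
      cfg <- config$scratch_config
      cfg$seed <- models$seeds[i]
      train_model(build_model(models$spec, seed = models$seeds[i]),
                  labeled, val, cfg)
    })
    models <- new_ensemble(members, source_models$seeds)
    stages <- c(stages, "scratch")
  }
  if (config$use_transfer) {
    members <- lapply(models$members, transfer_learn,
                      labeled_target_train = labeled,
                      labeled_target_val = val, config = config)
    models <- new_ensemble(members, models$seeds)
    stages <- c(stages, "transfer")
  }
  if (config$use_selflearn) {
    models <- self_learning(models, labeled, unlabeled, val, config)
    stages <- c(stages, "self-learning")
  }
  report <- list(
    stages = stages,
    seeds = models$seeds,
    k = length(models$members),
    config = config,
    val_dsc = evaluate_ensemble_dsc(models, val, config$policy),
    test_dsc = evaluate_ensemble_dsc(models, test, config$policy),
    sl_report = models$sl_report
  )
  list(ensemble = models, report = report)
}

#' Ablation-arm configuration
#'
#' Maps an ablation arm name to the corresponding adaptation switches:
#' `source-only` (no adaptation), `scratch` (random init, supervised on
#' labeled target), `tl` (transfer learning only, single model), `tl-sl`
#' (transfer + self-learning, single model, fixed weight), `tl-ens`
#' (transfer + ensemble self-learning, fixed weight), `ens-h` (ensemble
#' self-learning with entropy weights, no transfer stage), `tl-ens-h`
#' (the full pipeline).
#'
#' @param arm one of the arm names above.
#' @param base an [adaptation_config()] supplying rates and budgets.
#' @return a modified `segda_adaptation_config`.
#' @export
arm_config <- function(arm = c("source-only", "scratch", "tl", "tl-sl",
                               "tl-ens", "ens-h", "tl-ens-h"),
                       base = adaptation_config()) {
  arm <- match.arg(arm)
  cfg <- base
  cfg$init <- "source"
  cfg$use_transfer <- arm %in% c("tl", "tl-sl", "tl-ens", "tl-ens-h")
  cfg$use_selflearn <- arm %in% c("tl-sl", "tl-ens", "ens-h", "tl-ens-h")
  cfg$use_ensemble <- arm %in% c("tl-ens", "ens-h", "tl-ens-h", "source-only",
                                 "scratch")
  if (arm == "scratch") {
    cfg$init <- "scratch"
    cfg$use_ensemble <- FALSE
  }
  if (arm == "source-only") cfg$use_ensemble <- FALSE
  cfg$pseudo_weight_mode <- if (arm %in% c("ens-h", "tl-ens-h")) "entropy" else "fixed"
  cfg
}

#' Run several ablation arms on one cohort
#'
#' Convenience wrapper reproducing the ablation layout: each arm is run
#' with [run_domain_adaptation()] under [arm_config()] and the mean
#' foreground test DSCs are collected into one tibble.
#'
#' @param source_models source-domain models (see [run_domain_adaptation()]).
#' @param target_cohort a `segda_cohort`.
#' @param arms character vector of arm names.
#' @param base an [adaptation_config()].
#' @return tibble with columns `arm`, `val_dsc`, `test_dsc`.
#' @export
run_ablation_study <- function(source_models, target_cohort,
                               arms = c("source-only", "scratch", "tl",
                                        "tl-ens-h"),
                               base = adaptation_config()) {
  rows <- lapply(arms, function(arm) {
    res <- run_domain_adaptation(source_models, target_cohort,
                                 arm_config(arm, base))
    tibble(arm = arm, val_dsc = res$report$val_dsc,
           test_dsc = res$report$test_dsc)
  })
  dplyr::bind_rows(rows)
}
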