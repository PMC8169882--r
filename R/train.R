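#' Training configuration
#'
#' Defaults follow the supervised training schedule of the method: Adam
#' with learning rate 1e-3, batch size 2, at most 300 epochs, early
#' stopping when the validation loss has not improved for `patience = 40`
#' epochs, and reduce-on-plateau learning-rate decay (halved after
#' `ceiling(patience / 2)` stagnant epochs).  For desk-scale synthetic runs
#' pass a much smaller `max_epochs`.  `trainable_groups` restricts updates
#' to a subset of the encoder / bottleneck / decoder partition (used by
#' stage-I transfer learning, which freezes the decoder).
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param max_epochs maximum number of epochs.
#' @param batch_size cases per gradient step.
#' @param patience early-stopping patience in epochs (<= `max_epochs`).
#' @param lr_decay `"plateau"` (halve on stagnation) or `"none"`.
#' @param trainable_groups subset of `c("encoder", "bottleneck", "decoder")`.
#' @param loss `"dice"` (full supervision) or `"partial_dice"` (honours
#'   per-case masks and weights).
#' @param seed integer seed controlling shuffling and augmentation.
#' @param augment_flip apply random left-right flipping during training.
#' @param val_metric `"loss"` or `"dsc"`: quantity used for early stopping
#'   and best-snapshot selection.
#' @return an object of class `segda_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, max_epochs = 300L,
                         batch_size = 2L, patience = 40L,
                         lr_decay = c("plateau", "none"),
                         trainable_groups = c("encoder", "bottleneck", "decoder"),
                         loss = c("dice", "partial_dice"),
                         seed = 1L, augment_flip = TRUE,
                         val_metric = c("loss", "dsc")) {
  if (learning_rate <= 0) {
    abort("`learning_rate` must be > 0.", class = "segda_usage_error")
  }
  if (patience > max_epochs) {
    abort("`patience` must not exceed `max_epochs`.", class = "segda_usage_error")
  }
  trainable_groups <- match.arg(trainable_groups,
                                c("encoder", "bottleneck", "decoder"),
                                several.ok = TRUE)
  structure(
    list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         lr_decay = match.arg(lr_decay), trainable_groups = trainable_groups,
         loss = match.arg(loss), seed = as.integer(seed),
         augment_flip = isTRUE(augment_flip),
         val_metric = match.arg(val_metric)),
    class = "segda_train_config"
  )
}

# Normalize a heterogeneous case record into the tensors the loop needs.
prepare_train_case <- function(case, spec, honour_mask) {
  vol <- case$volume
  labels <- case$labels
  if (is.null(labels)) {
    abort("training cases must carry labels (or pseudo-labels).",
          class = "segda_usage_error")
  }
  dims <- dim(vol$data)
  check_input_dims(spec, dims)
  M <- if (honour_mask && !is.null(case$mask)) {
    as.numeric(case$mask)
  } else if (honour_mask) {
    as.numeric(label_mask(labels))
  } else {
    rep(1, prod(dims))
  }
  list(x = matrix(as.numeric(vol$data), nrow = spec$in_channels),
       Y = one_hot(labels), M = M,
       w = if (honour_mask) (case$weight %||% 1) else 1,
       dims = dims)
}

flip_perm <- function(dims) {
  W <- dims[1]
  idx <- seq_len(prod(dims)) - 1L
  x <- idx %% W
  as.integer(idx - x + (W - 1L - x)) + 1L
}

adam_init <- function(params, names) {
  st <- lapply(params[names], function(p) {
    list(m = p * 0, v = p * 0)
  })
  list(state = st, t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(opt$state)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    s <- opt$state[[nm]]
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] - lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
    opt$state[[nm]] <- s
  }
  list(params = params, opt = opt)
}

# Mean validation loss and mean foreground DSC over validation cases.
validate_model <- function(model, val_prepped) {
  losses <- numeric(length(val_prepped))
  dscs <- numeric(length(val_prepped))
  for (i in seq_along(val_prepped)) {
    vc <- val_prepped[[i]]
    fw <- nn_forward(model, vc$x, vc$dims, keep_cache = FALSE)
    losses[i] <- partial_dice_terms(fw$probs, vc$Y, rep(1, ncol(fw$probs)),
                                    1, DICE_EPS)$loss
    pred <- max.col(t(fw$probs), ties.method = "first") - 1L
    gt <- max.col(t(vc$Y), ties.method = "first") - 1L
    C <- nrow(fw$probs)
    ds <- vapply(seq_len(C - 1), function(cl) {
      px <- pred == cl; gx <- gt == cl
      inter <- sum(px & gx)
      tot <- sum(px) + sum(gx)
      if (tot == 0) 1 else 2 * inter / tot
    }, 0)
    dscs[i] <- mean(ds)
  }
  list(loss = mean(losses), dsc = mean(dscs))
}

#' Train a segmentation model
#'
#' Mini-batch Adam training with the (partial) Dice loss, optional random
#' left-right flip augmentation, reduce-on-plateau learning-rate decay and
#' early stopping on the validation metric.  The returned model carries the
#' weight snapshot with the best validation performance seen during
#' training; only parameters in `config$trainable_groups` are updated,
#' all others are returned bit-identical.
#'
#' Cases are lists with a `volume` and a `labels` entry; for
#' `loss = "partial_dice"` an optional `mask` (defaults to
#' [label_mask()] of the labels) and scalar `weight` (default 1) are
#' honoured per case.
#'
#' @param model a [build_model()] result (the initialization).
#' @param train_cases,val_cases non-empty lists of case records.
#' @param config a [train_config()].
#' @return the trained `segda_model`, with a `history` tibble (epoch,
#'   train_loss, val_loss, val_dsc, lr) and the config attached.
#' @export
train_model <- function(model, train_cases, val_cases, config = train_config()) {
  stopifnot(inherits(model, "segda_model"),
            inherits(config, "segda_train_config"))
  if (length(train_cases) == 0) {
    abort("`train_cases` must not be empty.", class = "segda_usage_error")
  }
  if (length(val_cases) == 0) {
    abort("`val_cases` must not be empty.", class = "segda_usage_error")
  }
  honour_mask <- config$loss == "partial_dice"
  tr <- lapply(train_cases, prepare_train_case, spec = model$spec,
               honour_mask = honour_mask)
  va <- lapply(val_cases, prepare_train_case, spec = model$spec,
               honour_mask = FALSE)
  groups <- parameter_groups(model)
  trainable <- unlist(groups[config$trainable_groups], use.names = FALSE)
  opt <- adam_init(model$params, trainable)
  perms <- lapply(tr, function(cs) flip_perm(cs$dims))

  set.seed(config$seed)
  lr <- config$learning_rate
  best_metric <- Inf
  best_params <- model$params
  best_epoch <- 0L
  stall <- 0L
  decay_stall <- 0L
  hist <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    order <- sample.int(length(tr))
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    epoch_loss <- 0
    for (batch in batches) {
      grads_acc <- NULL
      bl <- 0
      for (ci in batch) {
        cs <- tr[[ci]]
        x <- cs$x; Y <- cs$Y; M <- cs$M
        if (config$augment_flip && runif(1) < 0.5) {
          p <- perms[[ci]]
          x <- x[, p, drop = FALSE]
          Y <- Y[, p, drop = FALSE]
          M <- M[p]
        }
        fw <- nn_forward(model, x, cs$dims, keep_cache = TRUE)
        lg <- partial_dice_with_grad(fw$probs, Y, M, cs$w)
        bl <- bl + lg$loss
        g <- nn_backward(model, fw, lg$dP / length(batch))
        grads_acc <- if (is.null(grads_acc)) {
          g
        } else {
          purrr::map2(grads_acc, g[names(grads_acc)], `+`)
        }
      }
      epoch_loss <- epoch_loss + bl
      st <- adam_step(model$params, grads_acc, opt, lr)
      model$params <- st$params
      opt <- st$opt
    }
    vl <- validate_model(model, va)
    metric <- if (config$val_metric == "loss") vl$loss else -vl$dsc
    hist[[epoch]] <- tibble(epoch = epoch,
                            train_loss = epoch_loss / length(tr),
                            val_loss = vl$loss, val_dsc = vl$dsc, lr = lr)
    if (metric < best_metric - 1e-12) {
      best_metric <- metric
      best_params <- model$params
      best_epoch <- epoch
      stall <- 0L
      decay_stall <- 0L
    } else {
      stall <- stall + 1L
      decay_stall <- decay_stall + 1L
      if (config$lr_decay == "plateau" &&
          decay_stall >= ceiling(config$patience / 2)) {
        lr <- lr / 2
        decay_stall <- 0L
      }
      if (stall >= config$patience) break
    }
  }
  model$params <- best_params
  model$history <- dplyr::bind_rows(hist)
  model$best_epoch <- best_epoch
  model$train_config <- config
  model
}
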