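#' Train a deep ensemble of segmentation models
#'
#' Trains `k` networks that differ in their random weight initialization,
#' mini-batch order and (optionally) a per-member reshuffled
#' training/validation split, the three sources of minima variability the
#' ensembling exploits.  Member `i` is controlled entirely by `seeds[i]`.
#'
#' @param spec a [model_spec()] shared by all members.
#' @param train_cases,val_cases labeled case lists.
#' @param k ensemble size (>= 1); the uncertainty-weighted pipeline uses 5
#'   at full scale.
#' @param seeds integer vector of length `k`; duplicated seeds trigger a
#'   warning because the corresponding members coincide.
#' @param config a [train_config()] applied to every member (its `seed`
#'   field is replaced by the member seed).
#' @param resplit reshuffle the train/val split per member (keeping the
#'   two set sizes).
#' @return an object of class `segda_ensemble`:
#'   `list(members, seeds, spec)`.
#' @export
train_ensemble <- function(spec, train_cases, val_cases, k = 5L,
                           seeds = seq_len(k), config = train_config(),
                           resplit = TRUE) {
  k <- as.integer(k)
  if (k < 1) abort("`k` must be >= 1.", class = "segda_usage_error")
  if (length(seeds) != k) {
    abort("`seeds` must have length `k`.", class = "segda_usage_error")
  }
  if (anyDuplicated(seeds)) {
    warn("duplicate member seeds: the corresponding ensemble members will coincide.")
  }
  pool <- c(train_cases, val_cases)
  n_tr <- length(train_cases)
  members <- vector("list", k)
  for (i in seq_len(k)) {
    if (resplit) {
      set.seed(seeds[i])
      idx <- sample.int(length(pool))
      tr_i <- pool[idx[seq_len(n_tr)]]
      va_i <- pool[idx[-seq_len(n_tr)]]
    } else {
      tr_i <- train_cases
      va_i <- val_cases
    }
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    init <- build_model(spec, seed = seeds[i])
    members[[i]] <- train_model(init, tr_i, va_i, cfg)
  }
  new_ensemble(members, seeds)
}

new_ensemble <- function(members, seeds) {
  structure(list(members = members, seeds = as.integer(seeds),
                 spec = members[[1]]$spec),
            class = "segda_ensemble")
}

#' Wrap existing models as an ensemble
#'
#' @param members list of `segda_model`s sharing one specification.
#' @param seeds optional member seeds (defaults to each model's build seed).
#' @return a `segda_ensemble`.
#' @export
as_ensemble <- function(members, seeds = NULL) {
  if (length(members) < 1) abort("need at least one member.", class = "segda_usage_error")
  seeds <- seeds %||% vapply(members, function(m) as.integer(m$seed), 0L)
  new_ensemble(members, seeds)
}

#' @export
print.segda_ensemble <- function(x, ...) {
  cat(sprintf("<segda_ensemble> k = %d members, seeds: %s\n",
              length(x$members), paste(x$seeds, collapse = ", ")))
  invisible(x)
}

#' Ensemble-mean probability map
#'
#' The voxelwise arithmetic mean of the member softmax outputs,
#' `mu = (1/k) * sum_i f(x, theta_i)`; per-voxel class probabilities still
#' sum to 1.  This mean is the basis for pseudo-labels and for the entropy
#' uncertainty measure.
#'
#' @param ensemble a `segda_ensemble` (or a single `segda_model`, treated
#'   as a singleton ensemble).
#' @param vol a [volume()].
#' @return a [prob_map()].
#' @export
ensemble_mean <- function(ensemble, vol) {
  if (inherits(ensemble, "segda_model")) ensemble <- as_ensemble(list(ensemble))
  stopifnot(inherits(ensemble, "segda_ensemble"))
  preds <- lapply(ensemble$members, predict_volume, vol = vol)
  mu <- Reduce(`+`, lapply(preds, `[[`, "probs")) / length(preds)
  prob_map(mu, preds[[1]]$dim, preds[[1]]$spacing, preds[[1]]$origin)
}

#' Majority vote of an ensemble
#'
#' Each member casts its per-voxel argmax class as a vote; the class with
#' the most votes wins, with ties broken in favour of the class with the
#' highest ensemble-mean probability.
#'
#' @inheritParams ensemble_mean
#' @return a [label_map()].
#' @export
majority_vote <- function(ensemble, vol) {
  if (inherits(ensemble, "segda_model")) ensemble <- as_ensemble(list(ensemble))
  stopifnot(inherits(ensemble, "segda_ensemble"))
  preds <- lapply(ensemble$members, predict_volume, vol = vol)
  majority_from_predictions(preds)
}

# Vote aggregation over a list of prob_maps (one per member).
majority_from_predictions <- function(preds) {
  C <- preds[[1]]$n_classes
  N <- prod(preds[[1]]$dim)
  votes <- matrix(0, C, N)
  for (p in preds) {
    cls <- max.col(t(p$probs), ties.method = "first")
    votes[cbind(cls, seq_len(N))] <- votes[cbind(cls, seq_len(N))] + 1
  }
  mu <- Reduce(`+`, lapply(preds, `[[`, "probs")) / length(preds)
  # adding the mean probability (< 1) breaks vote ties without ever
  # overturning a strict vote majority
  score <- votes + mu
  cls <- max.col(t(score), ties.method = "first") - 1L
  label_map(array(cls, preds[[1]]$dim), preds[[1]]$spacing,
            preds[[1]]$origin, n_classes = C)
}

#' Per-voxel predictive entropy of a probability map
#'
#' `H = -sum_c mu_c log(mu_c)` in nats, with `0 * log(0) := 0`.  For C
#' classes the entropy lies in `[0, log(C)]`.
#'
#' @param mu a [prob_map()].
#' @return 3D numeric array of entropies.
#' @export
voxel_entropy <- function(mu) {
  stopifnot(inherits(mu, "segda_probmap"))
  p <- mu$probs
  if (any(p < -1e-8 | p > 1 + 1e-8)) {
    abort("probabilities must lie in [0, 1].", class = "segda_usage_error")
  }
  terms <- p * log(p)
  terms[p <= 0] <- 0
  array(-colSums(terms), mu$dim)
}

#' Case-level entropy
#'
#' The mean of [voxel_entropy()] over all voxels of the case: the scalar
#' uncertainty that is max-normalized across the pseudo-label pool to form
#' sample weights.
#'
#' @param mu a [prob_map()].
#' @return scalar mean entropy (nats).
#' @export
case_entropy <- function(mu) {
  mean(voxel_entropy(mu))
}

#' Entropy-derived sample weights
#'
#' Normalizes the case entropies by their maximum and sets
#' `w_i = 1 - H_i / max_j H_j`, so the most uncertain case gets weight 0.
#' If every entropy is 0 (all members fully confident everywhere) all
#' weights are 1.  Weights are invariant to the logarithm base used for
#' the entropy, because any base factor cancels in the normalization.
#'
#' @param case_entropies non-negative numeric vector.
#' @return numeric vector of weights in `[0, 1]`.
#' @export
entropy_weights <- function(case_entropies) {
  h <- as.numeric(case_entropies)
  if (length(h) == 0) return(numeric(0))
  if (any(h < 0)) abort("entropies must be >= 0.", class = "segda_usage_error")
  mx <- max(h)
  if (mx == 0) return(rep(1, length(h)))
  1 - h / mx
}
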