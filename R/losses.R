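# Multi-class soft Dice training loss and the masked, sample-weighted
# partial Dice loss used during self-learning.

DICE_EPS <- 1e-5

as_prob_matrix <- function(P) {
  if (inherits(P, "segda_probmap")) return(P$probs)
  if (is.matrix(P)) return(P)
  abort("`P` must be a prob_map or a (classes x voxels) matrix.",
        class = "segda_usage_error")
}

as_onehot_matrix <- function(Y, n_classes = NULL) {
  if (is_labelmap(Y)) return(one_hot(Y))
  if (is.matrix(Y)) return(Y)
  abort("`Y` must be a label_map or a (classes x voxels) one-hot matrix.",
        class = "segda_usage_error")
}

as_mask_vector <- function(M, n_voxels) {
  m <- as.numeric(M)
  if (length(m) != n_voxels || any(!(m %in% c(0, 1)))) {
    abort("`M` must be a binary mask with one value per voxel.",
          class = "segda_usage_error")
  }
  m
}

#' Multi-class soft Dice loss
#'
#' The negative mean over classes of the soft Dice coefficient
#' `2 * sum(P_c Y_c) / (sum(P_c) + sum(Y_c) + eps)`; a perfect prediction
#' scores -1 (up to the smoothing `eps`), no overlap in any class scores 0.
#' The background channel is included in the mean by default and can be
#' excluded.
#'
#' @param P a [prob_map()] or `(classes x voxels)` probability matrix.
#' @param Y a [label_map()] (fully labeled) or one-hot matrix of the same
#'   shape as `P`.
#' @param eps additive smoothing in the denominator.
#' @param include_background include class 0 in the class mean.
#' @return scalar loss in approximately `[-1, 0]`.
#' @export
dice_loss <- function(P, Y, eps = DICE_EPS, include_background = TRUE) {
  Pm <- as_prob_matrix(P)
  Ym <- as_onehot_matrix(Y)
  if (!all(dim(Pm) == dim(Ym))) {
    abort("`P` and `Y` must share geometry and class count.",
          class = "segda_usage_error")
  }
  partial_dice_loss(Pm, Ym, M = rep(1, ncol(Pm)), w = 1, eps = eps,
                    include_background = include_background)
}

#' Voxel mask of labeled voxels
#'
#' Returns 1 where a voxel carries any label and 0 where it is
#' [UNLABELED] (equivalently: where the one-hot row sums to zero).  The
#' partial Dice loss accounts only for voxels with mask 1.
#'
#' @param Y a [label_map()] possibly containing [UNLABELED] voxels.
#' @return 3D integer 0/1 array with the geometry of `Y`.
#' @export
label_mask <- function(Y) {
  stopifnot(is_labelmap(Y))
  array(as.integer(Y$data != UNLABELED), dim(Y$data))
}

#' Masked, sample-weighted partial Dice loss
#'
#' The self-learning loss: per class `c`,
#' `-(1/C) * sum_c w * 2 * sum_v(P_cv Y_cv M_v) /
#'  (sum_v(P_cv M_v) + sum_v(Y_cv M_v) + eps)`,
#' where `M` masks out unlabeled voxels and the scalar case weight
#' `w` in `[0, 1]` down-weights pseudo-labeled cases.  The loss is exactly
#' linear in `w`; with `M` identically 1 and `w = 1` it reduces to
#' [dice_loss()].  A class with no mass inside the mask (in either `P` or
#' `Y`) contributes `w * 0 / eps = 0`, and an all-zero mask gives loss 0
#' (the case contributes no gradient).
#'
#' @param P,Y as in [dice_loss()]; `Y` may contain [UNLABELED] voxels,
#'   whose one-hot rows are all zero.
#' @param M binary voxel mask (3D array or vector), typically
#'   [label_mask()] of the pseudo-label.
#' @param w scalar sample weight in `[0, 1]`.
#' @param eps additive smoothing in the denominator.
#' @param include_background include class 0 in the class mean.
#' @return scalar loss.
#' @export
partial_dice_loss <- function(P, Y, M = NULL, w = 1, eps = DICE_EPS,
                              include_background = TRUE) {
  Pm <- as_prob_matrix(P)
  Ym <- as_onehot_matrix(Y)
  if (!all(dim(Pm) == dim(Ym))) {
    abort("`P` and `Y` must share geometry and class count.",
          class = "segda_usage_error")
  }
  if (!is.numeric(w) || length(w) != 1 || w < 0 || w > 1) {
    abort("`w` must be a scalar in [0, 1].", class = "segda_usage_error")
  }
  if (is.null(M)) M <- rep(1, ncol(Pm))
  Mv <- as_mask_vector(M, ncol(Pm))
  partial_dice_terms(Pm, Ym, Mv, w, eps, include_background)$loss
}

# Shared numerator/denominator computation; also used by the gradient.
partial_dice_terms <- function(Pm, Ym, Mv, w, eps, include_background = TRUE) {
  C <- nrow(Pm)
  cls <- if (include_background) seq_len(C) else 2:C
  PM <- Pm * rep(Mv, each = C)
  num <- 2 * rowSums(PM * Ym)
  den <- rowSums(PM) + as.numeric(Ym %*% Mv) + eps
  loss <- -(w / length(cls)) * sum(num[cls] / den[cls])
  list(loss = loss, num = num, den = den, cls = cls)
}

# Loss and gradient w.r.t. the probabilities, for the training loop.
partial_dice_with_grad <- function(Pm, Ym, Mv, w, eps = DICE_EPS,
                                   include_background = TRUE) {
  C <- nrow(Pm)
  t <- partial_dice_terms(Pm, Ym, Mv, w, eps, include_background)
  scale <- numeric(C)
  offs <- numeric(C)
  scale[t$cls] <- 2 / t$den[t$cls]
  offs[t$cls] <- t$num[t$cls] / t$den[t$cls]^2
  # d/dP_cv = -(w/|cls|) * M_v * (2 Y_cv / den_c - num_c / den_c^2)
  dP <- -(w / length(t$cls)) *
    (Ym * scale - offs) * rep(Mv, each = C)
  list(loss = t$loss, dP = dP)
}
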