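#' Compound segmentation losses
#'
#' Two training losses address the extreme foreground/background imbalance of
#' whole-body scans (negative voxels average 99.5% of a volume).
#'
#' The 2D loss is a soft Dice term plus a class-frequency-weighted binary
#' cross-entropy. The 3D loss adds a sensitivity term and a mean absolute
#' error term to the Dice term, penalising false negatives and pushing
#' probabilities away from 0.5:
#' \deqn{L_{3D} = \Big[1 - \frac{2|P \cap T|}{|P|+|T|}\Big]
#'   + \Big[1 - \frac{|P \cap T|}{|T|}\Big]
#'   + \frac{1}{|V|}\sum_v |y_v - \hat y_v|}
#' with soft cardinalities (\eqn{|P| = \sum_v \hat y_v},
#' \eqn{|P \cap T| = \sum_v y_v \hat y_v}). All ratio terms carry a smoothing
#' epsilon of 1e-6 in numerator and denominator, which also fixes the
#' empty-target conventions (both-empty Dice term = 0, empty-target
#' sensitivity term = 0).
#'
#' @name losses
NULL

LOSS_EPS <- 1e-6
PROB_CLIP <- 1e-7

check_same_shape <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    petseg_abort("prediction and target shapes differ", "shape_mismatch")
}

as_plain_array <- function(x) if (inherits(x, "voxel_grid")) x$data else x

#' Soft Dice loss term
#'
#' `1 - (2|P∩T| + eps) / (|P| + |T| + eps)` with soft cardinalities; 0 when
#' both prediction and target are identically zero.
#'
#' @param pred probabilities in \[0,1\] (array or `voxel_grid`).
#' @param target binary mask of the same shape.
#' @return scalar in \[0, 1\].
#' @export
soft_dice_term <- function(pred, target) {
  pred <- as_plain_array(pred); target <- as_plain_array(target)
  check_same_shape(pred, target)
  1 - (2 * sum(pred * target) + LOSS_EPS) / (sum(pred) + sum(target) + LOSS_EPS)
}

#' Weighted binary cross-entropy term
#'
#' Mean over voxels of `-(w * y * log(p) + (1 - y) * log(1 - p))` with the
#' positive class up-weighted by the inverse foreground frequency
#' `w = |V| / max(sum(y), 1)`. Probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` so the logs stay finite. `form = "printed"` evaluates
#' an alternative weighting in which the negative term is scaled by
#' `(1 - |V|/sum(y))` and the whole sum by `|V|/sum(y)` (mean-reduced); it is
#' provided for comparison only, is not used in training, and can be negative
#' because that factor drops below zero whenever the foreground is rare.
#'
#' @param pred probabilities; @param target binary mask.
#' @param form `"weighted"` (default) or `"printed"`.
#' @return scalar (nonnegative for `"weighted"`).
#' @export
weighted_bce_term <- function(pred, target, form = c("weighted", "printed")) {
  form <- match.arg(form)
  pred <- as_plain_array(pred); target <- as_plain_array(target)
  check_same_shape(pred, target)
  p <- pmin(pmax(pred, PROB_CLIP), 1 - PROB_CLIP)
  y <- target
  nv <- length(y)
  w <- nv / max(sum(y), 1)
  if (form == "weighted") {
    -mean(w * y * log(p) + (1 - y) * log(1 - p))
  } else {
    -mean(w * (y * log(p) + (1 - w) * (1 - y) * log(1 - p)))
  }
}

#' 2D compound loss (Dice + weighted cross-entropy)
#'
#' @param pred probabilities; @param target binary mask (same shape).
#' @return a `loss_report` with `dice_term`, `ce_term`, `total`.
#' @export
loss_2d <- function(pred, target) {
  dice <- soft_dice_term(pred, target)
  ce <- weighted_bce_term(pred, target)
  structure(list(dice_term = dice, ce_term = ce, total = dice + ce),
            class = "loss_report")
}

#' 3D compound loss (Dice + sensitivity + MAE)
#'
#' @param pred probabilities; @param target binary mask (same shape).
#' @return a `loss_report` with `dice_term`, `sensitivity_term`, `mae_term`,
#'   `total` (in \[0, 3\]).
#' @export
loss_3d <- function(pred, target) {
  pred <- as_plain_array(pred); target <- as_plain_array(target)
  check_same_shape(pred, target)
  dice <- soft_dice_term(pred, target)
  sens <- 1 - (sum(pred * target) + LOSS_EPS) / (sum(target) + LOSS_EPS)
  mae <- mean(abs(target - pred))
  structure(list(dice_term = dice, sensitivity_term = sens, mae_term = mae,
                 total = dice + sens + mae),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  terms <- x[setdiff(names(x), "total")]
  cat("<loss_report>",
      paste(sprintf("%s=%.6g", names(terms), unlist(terms)), collapse = ", "),
      sprintf("| total=%.6g\n", x$total))
  invisible(x)
}

# Gradients of the compound losses with respect to the predicted
# probabilities; used by the training loops (chained through the network's
# sigmoid in the backward pass).
grad_loss_2d <- function(pred, target) {
  p <- pmin(pmax(pred, PROB_CLIP), 1 - PROB_CLIP)
  y <- target
  sp <- sum(pred); st <- sum(y); si <- sum(pred * y)
  den <- sp + st + LOSS_EPS
  g_dice <- -(2 * y * den - (2 * si + LOSS_EPS)) / den^2
  nv <- length(y)
  w <- nv / max(st, 1)
  g_ce <- -(w * y / p - (1 - y) / (1 - p)) / nv
  g_ce[pred < PROB_CLIP | pred > 1 - PROB_CLIP] <- 0
  g_dice + g_ce
}

grad_loss_3d <- function(pred, target) {
  y <- target
  sp <- sum(pred); st <- sum(y); si <- sum(pred * y)
  den <- sp + st + LOSS_EPS
  g_dice <- -(2 * y * den - (2 * si + LOSS_EPS)) / den^2
  g_sens <- -y / (st + LOSS_EPS)
  g_mae <- sign(pred - y) / length(y)
  g_dice + g_sens + g_mae
}
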