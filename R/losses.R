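# Composite segmentation loss: weighted Dice loss plus categorical focal
# loss.  The count-form Dice, the two-class weighted Dice (weights on
# background and neuropil), the focal term and the lambda-mixed total are
# the exact training objective of the stage-2 model.

#' Loss configuration for the stage-2 segmenter
#'
#' @param dice_weights numeric length-2 `(w1 background, w2 neuropil)`;
#'   default `c(0.4, 0.6)` up-weights the neuropil class.
#' @param focal_gamma focusing parameter gamma >= 0 (default 2): larger
#'   values damp the loss of easily classified voxels.
#' @param focal_alpha per-class balancing factors
#'   `(alpha background, alpha neuropil)`; default `c(0.25, 0.75)`.
#' @param lambda_mix lambda >= 0 mixing the focal term into the total loss
#'   (default 1: equal consideration).
#' @param textbook_dice logical; `FALSE` (default) uses the two-class
#'   pooled weighted-Dice grouping
#'   `1 - 2*S / (2*S + sum(w*FN) + sum(w*FP))` with
#'   `S = w1*TP1 + w2*TP2`; `TRUE` uses the weighted mean of per-class
#'   Dice losses instead.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(dice_weights = c(0.4, 0.6), focal_gamma = 2,
                        focal_alpha = c(0.25, 0.75), lambda_mix = 1,
                        textbook_dice = FALSE) {
  assert_that(length(dice_weights) == 2 && all(dice_weights > 0),
              "dice_weights must be 2 positive numbers")
  assert_that(focal_gamma >= 0, "focal_gamma must be >= 0")
  assert_that(length(focal_alpha) == 2 && all(focal_alpha > 0),
              "focal_alpha must be 2 positive numbers")
  assert_that(lambda_mix >= 0, "lambda_mix must be >= 0")
  structure(list(dice_weights = dice_weights, focal_gamma = focal_gamma,
                 focal_alpha = focal_alpha, lambda_mix = lambda_mix,
                 textbook_dice = textbook_dice),
            class = "loss_config")
}

# coerce ground truth to an n x 2 one-hot matrix and predictions to an
# n x 2 probability matrix (accepts binary arrays, label_volumes, or
# (...,2)-shaped probability arrays)
as_onehot2 <- function(gt) {
  if (inherits(gt, "label_volume")) gt <- gt$data
  if (is.matrix(gt) && ncol(gt) == 2) return(gt)
  g <- as.numeric(gt > 0)
  cbind(1 - g, g)
}

as_probmat2 <- function(p) {
  if (inherits(p, "label_volume")) p <- p$data
  d <- dim(p)
  if (!is.null(d) && length(d) > 2 && d[length(d)] == 2)
    return(matrix(p, ncol = 2))
  if (is.matrix(p) && ncol(p) == 2) return(p)
  pos <- as.numeric(p)
  cbind(1 - pos, pos)
}

#' Dice loss (soft form)
#'
#' `1 - 2 |Y_true & Y_pred| / (|Y_true| + |Y_pred|)` over the positive
#' class, with the soft intersection `sum(gt * p)` when `pred` holds
#' probabilities.  On hard predictions this equals the count form
#' `1 - 2 TP / (2 TP + FP + FN)`.  Both sets empty returns 0 (an
#' all-background region predicted all-background is a perfect prediction).
#'
#' @param gt binary ground-truth mask (array, vector or [label_volume()]).
#' @param pred binary mask or per-voxel positive-class probabilities,
#'   aligned with `gt`.
#' @return Numeric in [0, 1].
#' @export
dice_loss <- function(gt, pred) {
  if (inherits(gt, "label_volume")) gt <- gt$data
  if (inherits(pred, "label_volume")) pred <- pred$data
  assert_that(length(gt) == length(pred), "gt and pred must be the same size")
  g <- as.numeric(gt > 0)
  p <- as.numeric(pred)
  denom <- sum(g) + sum(p)
  if (denom == 0) return(0)
  1 - 2 * sum(g * p) / denom
}

#' Dice loss from confusion counts
#'
#' `1 - 2 TP / (2 TP + FP + FN)`; all-zero counts return 0.
#'
#' @param tp,fp,fn voxel counts.
#' @return Numeric in [0, 1].
#' @export
dice_loss_counts <- function(tp, fp, fn) {
  denom <- 2 * tp + fp + fn
  if (denom == 0) return(0)
  1 - 2 * tp / denom
}

#' Weighted two-class Dice loss
#'
#' With per-class weights `w = (w1, w2)` on background and neuropil and
#' matched term `S = w1*TP1 + w2*TP2`:
#' `1 - 2*S / (2*S + (w1*FN1 + w2*FN2) + (w1*FP1 + w2*FP2))`.
#' Reduces to the pooled unweighted Dice loss when `w1 == w2`.  All-zero
#' counts return 0.
#'
#' @param counts a [confusion_counts()] (or any list with `tp`, `fp`, `fn`
#'   length-2 vectors ordered background, neuropil).
#' @param w per-class weights, default `c(0.4, 0.6)`.
#' @param textbook logical; `TRUE` returns the weighted mean of per-class
#'   Dice losses instead of the pooled grouping.
#' @return Numeric in [0, 1].
#' @export
weighted_dice_loss <- function(counts, w = c(0.4, 0.6), textbook = FALSE) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  assert_that(length(tp) == 2 && length(fp) == 2 && length(fn) == 2,
              "counts must carry per-class tp/fp/fn for 2 classes")
  if (textbook) {
    per_class <- vapply(1:2, function(t) dice_loss_counts(tp[t], fp[t], fn[t]), numeric(1))
    return(sum(w * per_class) / sum(w))
  }
  s <- sum(w * tp)
  denom <- 2 * s + sum(w * fn) + sum(w * fp)
  if (denom == 0) return(0)
  1 - 2 * s / denom
}

#' Categorical focal loss
#'
#' Per-voxel `-g_t * alpha_t * (1 - p_t)^gamma * log(p_t)` summed over the
#' two classes and averaged over voxels; probabilities are clipped to
#' `[1e-7, 1 - 1e-7]`.  At `gamma = 0`, `alpha = (1, 1)` this is the mean
#' cross-entropy.
#'
#' @param gt_onehot ground truth: n x 2 one-hot matrix or a binary mask
#'   (coerced to one-hot).
#' @param probs per-voxel class probabilities: n x 2 matrix or an array
#'   with trailing dimension 2; rows must sum to 1.
#' @param alpha per-class balancing factors.
#' @param gamma focusing parameter.
#' @return Numeric >= 0.
#' @export
categorical_focal_loss <- function(gt_onehot, probs, alpha = c(0.25, 0.75), gamma = 2) {
  g <- as_onehot2(gt_onehot)
  p <- as_probmat2(probs)
  assert_that(nrow(g) == nrow(p), "gt and probs must be the same size")
  p <- clip01(p)
  per <- -g * rep(alpha, each = nrow(p)) * (1 - p)^gamma * log(p)
  sum(per) / nrow(p)
}

#' Total segmentation loss
#'
#' `WeightedDiceLoss + lambda * CategoricalFocalLoss`, with the weighted
#' Dice evaluated on soft confusion counts (`TP_t = sum(g_t * p_t)` etc.)
#' so probabilities and hard masks are both valid inputs.
#'
#' @param gt binary mask or one-hot matrix.
#' @param probs per-voxel class probabilities (see
#'   [categorical_focal_loss()]).
#' @param cfg a [loss_config()].
#' @return Numeric >= 0.
#' @export
total_loss <- function(gt, probs, cfg = loss_config()) {
  g <- as_onehot2(gt)
  p <- as_probmat2(probs)
  counts <- soft_confusion(g, p)
  wd <- weighted_dice_loss(counts, cfg$dice_weights, textbook = cfg$textbook_dice)
  fl <- categorical_focal_loss(g, p, cfg$focal_alpha, cfg$focal_gamma)
  wd + cfg$lambda_mix * fl
}

# soft per-class confusion counts from one-hot gt and probabilities
soft_confusion <- function(g, p) {
  tp <- colSums(g * p)
  fn <- colSums(g * (1 - p))
  fp <- colSums((1 - g) * p)
  tn <- colSums((1 - g) * (1 - p))
  confusion_counts(tp, fp, fn, tn)
}

# gradient of total_loss w.r.t. the probability matrix (n x 2); internal,
# used by the segmenter's training loop.  Derivation: with
# S = sum_t w_t TP_t, D = 2S + sum w FN + sum w FP, dD/dp_tv = w_t and
# dS/dp_tv = w_t g_tv, so dLdice/dp_tv = w_t (2S - 2 g_tv D) / D^2
# (pooled grouping).  Focal: d/dp[-g a (1-p)^g log p] =
# -g a [ (1-p)^g / p - gamma (1-p)^(gamma-1) log p ].
total_loss_grad <- function(g, p, cfg = loss_config()) {
  n <- nrow(p)
  w <- cfg$dice_weights
  pc <- clip01(p)
  tp <- colSums(g * pc); fn <- colSums(g * (1 - pc)); fp <- colSums((1 - g) * pc)
  s <- sum(w * tp)
  d <- 2 * s + sum(w * fn) + sum(w * fp)
  ddice <- if (d == 0) matrix(0, n, 2) else {
    wm <- rep(w, each = n)
    wm * (2 * s - 2 * g * d) / d^2
  }
  gamma <- cfg$focal_gamma
  am <- rep(cfg$focal_alpha, each = n)
  omp <- 1 - pc
  dfocal <- -g * am * (omp^gamma / pc - gamma * omp^pmax(gamma - 1, 0) * log(pc)) / n
  dfocal[p <= 1e-7 & g == 0] <- 0   # clipped region: no gradient
  ddice + cfg$lambda_mix * dfocal
}
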