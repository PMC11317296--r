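# Segmentation quality metrics (recall, precision, F1, 3D IoU) and
# annotator/model consistency.

#' Per-class confusion counts
#'
#' @param tp,fp,fn,tn numeric length-2 vectors of voxel counts, ordered
#'   (background, neuropil).  Soft (fractional) counts are allowed.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  assert_that(all(c(tp, fp, fn, tn) >= -1e-9), "counts must be non-negative")
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn), tn = as.numeric(tn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts (background, neuropil):\n")
  for (f in c("tp", "fp", "fn", "tn"))
    cat(sprintf("  %s: %s\n", toupper(f), paste(signif(x[[f]], 6), collapse = ", ")))
  invisible(x)
}

#' Voxel-wise confusion counts between two label volumes
#'
#' @param gt,pred aligned [label_volume()]s (or binary arrays).
#' @param positive_class class index treated as the neuropil class
#'   (default 1; everything else is background).
#' @return A [confusion_counts()] whose per-class totals sum to the voxel
#'   count.
#' @export
confusion <- function(gt, pred, positive_class = 1) {
  if (inherits(gt, "label_volume")) gt <- gt$data
  if (inherits(pred, "label_volume")) pred <- pred$data
  assert_that(identical(dim(gt), dim(pred)), "gt and pred shapes must match")
  g <- gt == positive_class
  p <- pred == positive_class
  tp2 <- sum(g & p); fp2 <- sum(!g & p); fn2 <- sum(g & !p); tn2 <- sum(!g & !p)
  # background is the complement class: its TP are the true negatives above
  confusion_counts(tp = c(tn2, tp2), fp = c(fn2, fp2),
                   fn = c(fp2, fn2), tn = c(tp2, tn2))
}

#' Segmentation metrics from confusion counts
#'
#' Recall `TP/(TP+FN)`, precision `TP/(TP+FP)`, F1 and 3D IoU
#' `TP/(TP+FP+FN)` for the neuropil class.  Conventions for empty sets:
#' empty ground truth and empty prediction give all metrics 1; an undefined
#' 0/0 ratio with a nonempty counterpart is reported as 0 and flagged in
#' the `undefined` field.
#'
#' @param counts a [confusion_counts()].
#' @return An object of class `seg_metrics` with fields `recall`,
#'   `precision`, `f1`, `iou3d`, `undefined` (character vector of metrics
#'   that hit an undefined 0/0).
#' @export
seg_metrics <- function(counts) {
  tp <- counts$tp[2]; fp <- counts$fp[2]; fn <- counts$fn[2]
  undefined <- character(0)
  if (tp + fp + fn == 0) {
    out <- list(recall = 1, precision = 1, f1 = 1, iou3d = 1, undefined = undefined)
    return(structure(out, class = "seg_metrics"))
  }
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  recall <- ratio(tp, tp + fn, "recall")
  precision <- ratio(tp, tp + fp, "precision")
  f1 <- ratio(2 * tp, 2 * tp + fp + fn, "f1")
  iou <- ratio(tp, tp + fp + fn, "iou3d")
  structure(list(recall = recall, precision = precision, f1 = f1,
                 iou3d = iou, undefined = undefined),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("recall %.4f  precision %.4f  F1 %.4f  3D-IoU %.4f%s\n",
              x$recall, x$precision, x$f1, x$iou3d,
              if (length(x$undefined)) paste0("  [undefined: ",
                paste(x$undefined, collapse = ","), "]") else ""))
  invisible(x)
}

#' 3D intersection-over-union of two binary masks
#'
#' @param a,b aligned binary masks (arrays or [label_volume()]s).
#' @return `|A & B| / |A | B|`; 1 when both are empty.
#' @export
iou3d <- function(a, b) {
  if (inherits(a, "label_volume")) a <- a$data
  if (inherits(b, "label_volume")) b <- b$data
  assert_that(identical(dim(a), dim(b)), "mask shapes must match")
  ga <- a > 0; gb <- b > 0
  un <- sum(ga | gb)
  if (un == 0) return(1)
  sum(ga & gb) / un
}

#' Mean pairwise 3D IoU of a set of masks
#'
#' Consistency measure across annotators or models segmenting the same
#' volume: the mean 3D IoU over all unordered pairs.
#'
#' @param masks list of >= 2 aligned binary masks.
#' @return Numeric in [0, 1].
#' @export
pairwise_consistency <- function(masks) {
  assert_that(length(masks) >= 2, "need at least 2 masks")
  n <- length(masks)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    vals <- c(vals, iou3d(masks[[i]], masks[[j]]))
  mean(vals)
}
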