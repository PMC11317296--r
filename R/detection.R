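# Stage-1 ROI detection on Z-projections.
#
# The detector is a compact anchor-free single-stage model trained from
# scratch: the projection is resized to a square input, reduced to a cell
# grid of pooled intensity and position features, and a per-cell softmax
# classifier (background + 3 ROI classes, fitted with Adam) labels the
# grid.  Per-class connected cell components become boxes, expanded by
# per-class margins calibrated on the training set so that boxes cover the
# full structure, then merged by greedy NMS with at most one box retained
# per class and bilateral side.  Detection quality is scored by mAP over
# IoU thresholds 0.5:0.95 and by the coverage-success criterion (a
# detection succeeds only if the box covers the entire structure).

#' Detector configuration
#'
#' @param input_size square input resolution the projection is resized to.
#' @param classes ROI class names.
#' @param epochs training epochs (one pass over all projection samples).
#' @param learning_rate Adam step size.
#' @param confidence_threshold minimum cell probability for detection.
#' @param nms_iou IoU threshold of the greedy non-maximum suppression.
#' @param cell cell size in input pixels (the grid is
#'   `input_size / cell` square).
#' @param seed RNG seed for shuffling; training is reproducible given the
#'   seed.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(input_size = 256, classes = ROI_CLASSES,
                            epochs = 30, learning_rate = 0.05,
                            confidence_threshold = 0.25, nms_iou = 0.5,
                            cell = 8, seed = 0) {
  assert_that(epochs >= 1, "epochs must be >= 1")
  assert_that(confidence_threshold > 0 && confidence_threshold <= 1,
              "confidence_threshold must be in (0, 1]")
  assert_that(nms_iou > 0 && nms_iou < 1, "nms_iou must be in (0, 1)")
  assert_that(input_size %% cell == 0, "input_size must be divisible by cell")
  structure(list(input_size = input_size, classes = classes, epochs = epochs,
                 learning_rate = learning_rate,
                 confidence_threshold = confidence_threshold,
                 nms_iou = nms_iou, cell = cell, seed = seed),
            class = "detector_config")
}

#' Intersection-over-union of two boxes
#'
#' Area IoU on half-open pixel rectangles: symmetric, 1 for identical
#' boxes, 0 for disjoint boxes.
#'
#' @param a,b [bounding_box()] objects.
#' @return Numeric in [0, 1].
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  iy <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- ix * iy
  inter / (box_area(a) + box_area(b) - inter)
}

#' Coverage success of a detection
#'
#' A detection succeeds only when the box covers the entire structure:
#' every nonzero mask pixel lies inside the (half-open) box.
#'
#' @param box a [bounding_box()].
#' @param gt_mask_projection nonempty 2D (Y, X) binary mask of the
#'   structure's Z-projection.
#' @return Logical.
#' @export
coverage_success <- function(box, gt_mask_projection) {
  px <- which(gt_mask_projection > 0, arr.ind = TRUE)
  assert_that(nrow(px) > 0, "empty ground-truth mask")
  xs <- px[, 2] - 1; ys <- px[, 1] - 1      # 0-based pixel coords
  all(xs >= box$x0 & xs < box$x1 & ys >= box$y0 & ys < box$y1)
}

# ---- features ------------------------------------------------------------

cell_mean <- function(m, cell) {
  g1 <- nrow(m) / cell; g2 <- ncol(m) / cell
  s <- rowsum(m, rep(seq_len(g1), each = cell))
  t(rowsum(t(s), rep(seq_len(g2), each = cell))) / cell^2
}

cell_max <- function(m, cell) {
  red <- function(mm) {
    n <- nrow(mm)
    out <- mm[seq(1, n, cell), , drop = FALSE]
    for (k in 2:cell) out <- pmax(out, mm[seq(k, n, cell), , drop = FALSE])
    out
  }
  t(red(t(red(m))))
}

smooth_box2 <- function(m) {
  pad_shift <- function(mm, dr, dc) {
    n <- nrow(mm); p <- ncol(mm)
    out <- matrix(0, n, p)
    rs <- max(1, 1 + dr):min(n, n + dr)
    cs <- max(1, 1 + dc):min(p, p + dc)
    out[rs, cs] <- mm[rs - dr, cs - dc]
    out
  }
  (pad_shift(m, -1, 0) + m + pad_shift(m, 1, 0)) / 3 -> m
  (pad_shift(m, 0, -1) + m + pad_shift(m, 0, 1)) / 3
}

# per-cell feature matrix (g^2 x p) for one projection image
detector_features <- function(proj, cfg) {
  img <- if (inherits(proj, "projection2d")) proj$data else proj
  img <- resize_bilinear(img, cfg$input_size, cfg$input_size) / 255
  g <- cfg$input_size / cfg$cell
  cm <- cell_mean(img, cfg$cell)
  cx <- cell_max(img, cfg$cell)
  s1 <- smooth_box2(cm)
  s2 <- smooth_box2(s1)
  rown <- matrix((seq_len(g) - 0.5) / g, g, g)
  coln <- matrix((seq_len(g) - 0.5) / g, g, g, byrow = TRUE)
  cbind(1, as.vector(cm), as.vector(cx), as.vector(s1), as.vector(s2),
        as.vector(cm)^2, as.vector(rown), as.vector(coln),
        as.vector(abs(coln - 0.5)), as.vector(rown * as.vector(cm)))
}

# per-cell class labels (0 = background, else class index) for one image
detector_cell_labels <- function(boxes, proj_shape, cfg) {
  g <- cfg$input_size / cfg$cell
  sy <- cfg$input_size / proj_shape[1]; sx <- cfg$input_size / proj_shape[2]
  lab <- matrix(0L, g, g)
  area <- matrix(Inf, g, g)
  ccx <- (matrix(seq_len(g), g, g, byrow = TRUE) - 0.5) * cfg$cell
  ccy <- (matrix(seq_len(g), g, g) - 0.5) * cfg$cell
  for (b in boxes) {
    inside <- ccx >= b$x0 * sx & ccx < b$x1 * sx & ccy >= b$y0 * sy & ccy < b$y1 * sy
    a <- box_area(b)
    take <- inside & a < area
    lab[take] <- match(b$roi_class, cfg$classes)
    area[take] <- a
  }
  as.vector(lab)
}

#' Build an (untrained) detector
#'
#' A freshly built detector has zero weights and predicts the uniform
#' class distribution; it becomes useful after [train_detector()].
#'
#' @param cfg a [detector_config()].
#' @return An object of class `detector_model`.
#' @export
build_detector <- function(cfg = detector_config()) {
  n_feat <- ncol(detector_features(matrix(0, 16, 16), cfg))
  structure(list(W = matrix(0, n_feat, length(cfg$classes) + 1),
                 pads = stats::setNames(rep(2 * cfg$cell, length(cfg$classes)),
                                        cfg$classes),
                 cfg = cfg, fitted = FALSE),
            class = "detector_model")
}

#' Train the ROI detector
#'
#' Each projection (both modes of every brain should be included, so the
#' model sees a variety of brightness renderings) is one training sample.
#' The per-cell softmax classifier is fitted with Adam, one mini-batch per
#' image; after fitting, per-class box expansion margins are calibrated on
#' the training set so that extracted boxes cover their matched ground
#' truth.
#'
#' @param train_set list of samples `list(projection =, boxes =)` where
#'   `projection` is a [project()] result (or plain matrix) and `boxes` a
#'   nonempty list of [bounding_box()].  Use both projection modes of each
#'   brain as separate samples.
#' @param cfg a [detector_config()].
#' @return A fitted `detector_model`; training is deterministic given
#'   `cfg$seed`.
#' @export
train_detector <- function(train_set, cfg = detector_config()) {
  assert_that(length(train_set) >= 1, "empty training set")
  model <- build_detector(cfg)
  n_cls <- length(cfg$classes) + 1
  feats <- vector("list", length(train_set))
  labs <- vector("list", length(train_set))
  for (i in seq_along(train_set)) {
    s <- train_set[[i]]
    img <- if (inherits(s$projection, "projection2d")) s$projection$data else s$projection
    assert_that(length(s$boxes) >= 1, "training image %d has zero boxes", i)
    for (b in s$boxes)
      assert_that(b$x1 <= ncol(img) && b$y1 <= nrow(img) && b$x0 >= 0 && b$y0 >= 0,
                  "training box outside image %d", i)
    feats[[i]] <- detector_features(img, cfg)
    labs[[i]] <- detector_cell_labels(s$boxes, dim(img), cfg)
  }
  W <- model$W
  mW <- vW <- W * 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  with_seed(derive_seed(cfg$seed, 1), {
    for (ep in seq_len(cfg$epochs)) {
      for (i in sample(seq_along(train_set))) {
        X <- feats[[i]]
        y <- labs[[i]]
        Yh <- matrix(0, length(y), n_cls)
        Yh[cbind(seq_along(y), y + 1)] <- 1
        logits <- X %*% W
        logits <- logits - apply(logits, 1, max)
        P <- exp(logits); P <- P / rowSums(P)
        grad <- crossprod(X, P - Yh) / nrow(X)
        t <- t + 1
        mW <- b1 * mW + (1 - b1) * grad
        vW <- b2 * vW + (1 - b2) * grad^2
        W <- W - cfg$learning_rate * (mW / (1 - b1^t)) / (sqrt(vW / (1 - b2^t)) + eps)
      }
    }
  })
  model$W <- W
  model$fitted <- TRUE
  # calibrate per-class expansion pads (input-space pixels) on the
  # training set: every raw box matched to a same-class ground truth must
  # be expandable to cover it
  pads <- stats::setNames(rep(cfg$cell / 2, length(cfg$classes)), cfg$classes)
  for (i in seq_along(train_set)) {
    s <- train_set[[i]]
    img <- if (inherits(s$projection, "projection2d")) s$projection$data else s$projection
    raw <- detect_raw_boxes(model, img, cfg, pad = 0)
    for (b in raw) {
      gt_match <- NULL; best <- 0.1
      for (gb in s$boxes) if (gb$roi_class == b$roi_class) {
        v <- box_iou(gb, b)
        if (v > best) { best <- v; gt_match <- gb }
      }
      if (is.null(gt_match)) next
      sy <- cfg$input_size / nrow(img); sx <- cfg$input_size / ncol(img)
      need <- max(b$x0 - gt_match$x0 * sx, gt_match$x1 * sx - b$x1,
                  b$y0 - gt_match$y0 * sy, gt_match$y1 * sy - b$y1, 0)
      cls <- b$roi_class
      pads[cls] <- max(pads[cls], need + 2)
    }
  }
  model$pads <- pads
  model
}

# raw per-class component boxes in INPUT space (before pads/NMS/clipping
# to the original projection size)
detect_raw_boxes <- function(model, img, cfg, pad = NULL) {
  X <- detector_features(img, cfg)
  logits <- X %*% model$W
  logits <- logits - apply(logits, 1, max)
  P <- exp(logits); P <- P / rowSums(P)
  g <- cfg$input_size / cfg$cell
  out <- list()
  for (ci in seq_along(cfg$classes)) {
    pc <- matrix(P[, ci + 1], g, g)
    hot <- pc > cfg$confidence_threshold
    if (!any(hot)) next
    lab <- label_components(array(hot, c(1, g, g)), connectivity = 26)
    for (comp in seq_len(lab$n_components)) {
      cells <- lab$idx[lab$membership == comp]
      yc <- ((cells - 1) %% g) + 1
      xc <- ((cells - 1) %/% g) + 1
      p <- if (is.null(pad)) model$pads[cfg$classes[ci]] else pad
      out[[length(out) + 1]] <- bounding_box(
        cfg$classes[ci],
        (min(xc) - 1) * cfg$cell - p, (min(yc) - 1) * cfg$cell - p,
        max(xc) * cfg$cell + p, max(yc) * cfg$cell + p,
        confidence = max(pc[cbind(yc, xc)]))
    }
  }
  out
}

# Refine a coarse detection box against the projection image: inside the
# (padded) search box, threshold halfway between the dim and bright pixel
# populations and take the tight bounding box of the bright pixels, plus a
# small safety margin.  Recovers sub-cell box edges from the image itself.
refine_box_by_intensity <- function(img, box, margin = 2) {
  y0 <- max(0, floor(box$y0)); y1 <- min(nrow(img), ceiling(box$y1))
  x0 <- max(0, floor(box$x0)); x1 <- min(ncol(img), ceiling(box$x1))
  if (y1 - y0 < 2 || x1 - x0 < 2) return(box)
  sub <- img[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  thr <- (stats::quantile(sub, 0.05) + max(sub)) / 2
  hot <- which(sub > thr, arr.ind = TRUE)
  if (nrow(hot) == 0) return(box)
  bounding_box(box$roi_class,
               max(0, x0 + min(hot[, 2]) - 1 - margin),
               max(0, y0 + min(hot[, 1]) - 1 - margin),
               min(ncol(img), x0 + max(hot[, 2]) + margin),
               min(nrow(img), y0 + max(hot[, 1]) + margin),
               box$confidence)
}

# greedy NMS: keep highest-confidence boxes, drop same-class overlaps
nms_boxes <- function(boxes, iou_thr) {
  if (length(boxes) <= 1) return(boxes)
  ord <- order(-vapply(boxes, `[[`, numeric(1), "confidence"))
  keep <- list()
  for (i in ord) {
    b <- boxes[[i]]
    dup <- any(vapply(keep, function(k)
      k$roi_class == b$roi_class && box_iou(k, b) >= iou_thr, logical(1)))
    if (!dup) keep[[length(keep) + 1]] <- b
  }
  keep
}

#' Detect ROIs on a projection
#'
#' Cells above the confidence threshold are grouped into per-class
#' components, expanded by the calibrated margins, clipped to the image,
#' and merged by greedy NMS; at most one box per class and bilateral side
#' (split at the vertical image midline) is retained.
#'
#' @param model a `detector_model` (error if it carries no weights).
#' @param proj a [project()] result or (Y, X) matrix.
#' @param cfg optional [detector_config()] override (defaults to the
#'   model's).
#' @return List of [bounding_box()] in the projection's pixel coordinates.
#' @export
detect_rois <- function(model, proj, cfg = NULL) {
  assert_that(inherits(model, "detector_model") && !is.null(model$W),
              "untrained model: train_detector() first")
  cfg <- cfg %||% model$cfg
  img <- if (inherits(proj, "projection2d")) proj$data else proj
  raw <- detect_raw_boxes(model, img, cfg)
  if (length(raw) == 0) return(list())
  sy <- nrow(img) / cfg$input_size; sx <- ncol(img) / cfg$input_size
  mapped <- lapply(raw, function(b) {
    x0 <- max(0, b$x0 * sx); x1 <- min(ncol(img), b$x1 * sx)
    y0 <- max(0, b$y0 * sy); y1 <- min(nrow(img), b$y1 * sy)
    search <- bounding_box(b$roi_class, round(x0), round(y0), round(x1),
                           round(y1), b$confidence)
    refine_box_by_intensity(img, search)
  })
  kept <- nms_boxes(mapped, cfg$nms_iou)
  # at most one box per class per side (top confidence)
  mid <- ncol(img) / 2
  key <- vapply(kept, function(b)
    paste(b$roi_class, if ((b$x0 + b$x1) / 2 < mid) "L" else "R"), character(1))
  out <- list()
  for (k in unique(key)) {
    grp <- kept[key == k]
    best <- grp[[which.max(vapply(grp, `[[`, numeric(1), "confidence"))]]
    out[[length(out) + 1]] <- best
  }
  out
}

#' Detect ROIs from both projection modes of one brain
#'
#' Runs [detect_rois()] on the max and mean projections and merges the two
#' box sets by NMS and the per-class-per-side rule.
#'
#' @param model a fitted `detector_model`.
#' @param proj_pair result of [projection_pair()].
#' @param cfg optional config override.
#' @return List of [bounding_box()].
#' @export
detect_rois_pair <- function(model, proj_pair, cfg = NULL) {
  cfg <- cfg %||% model$cfg
  all_boxes <- c(detect_rois(model, proj_pair$max, cfg),
                 detect_rois(model, proj_pair$mean, cfg))
  if (length(all_boxes) == 0) return(list())
  img <- proj_pair$max$data
  kept <- nms_boxes(all_boxes, cfg$nms_iou)
  mid <- ncol(img) / 2
  key <- vapply(kept, function(b)
    paste(b$roi_class, if ((b$x0 + b$x1) / 2 < mid) "L" else "R"), character(1))
  out <- list()
  for (k in unique(key)) {
    grp <- kept[key == k]
    out[[length(out) + 1]] <- grp[[which.max(vapply(grp, `[[`, numeric(1), "confidence"))]]
  }
  out
}

# ---- mAP -----------------------------------------------------------------

#' Evaluate detections by mean average precision
#'
#' AP per class and IoU threshold via confidence-sorted greedy matching
#' (each ground truth matched at most once; among eligible ground truths
#' the highest-IoU one is taken) and all-point interpolation of the
#' precision-recall curve.  mAP averages over classes (those present in
#' the ground truth), and additionally over IoU thresholds 0.5 to 0.95 in
#' steps of 0.05 for `map50_95`.
#'
#' @param preds list (one entry per image) of predicted [bounding_box()]
#'   lists with confidences.
#' @param gts list (aligned with `preds`) of ground-truth box lists.
#' @param classes class names to evaluate.
#' @return An object of class `detection_eval`: `map50`, `map50_95`,
#'   `per_class_ap` (class x threshold matrix).
#' @export
evaluate_map <- function(preds, gts, classes = ROI_CLASSES) {
  assert_that(length(preds) == length(gts),
              "preds and gts must cover the same images")
  thresholds <- seq(0.5, 0.95, by = 0.05)
  ap <- matrix(NA_real_, length(classes), length(thresholds),
               dimnames = list(classes, sprintf("%.2f", thresholds)))
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    cls_gts <- lapply(gts, function(g) Filter(function(b) b$roi_class == cls, g))
    n_gt <- sum(lengths(cls_gts))
    if (n_gt == 0) next
    cls_preds <- list()
    for (i in seq_along(preds))
      for (b in preds[[i]]) if (b$roi_class == cls)
        cls_preds[[length(cls_preds) + 1]] <- list(img = i, box = b)
    for (ti in seq_along(thresholds)) {
      thr <- thresholds[ti]
      if (length(cls_preds) == 0) { ap[ci, ti] <- 0; next }
      conf <- vapply(cls_preds, function(p) p$box$confidence, numeric(1))
      ord <- order(-conf)
      matched <- lapply(cls_gts, function(g) rep(FALSE, length(g)))
      tp <- fp <- numeric(length(ord))
      for (k in seq_along(ord)) {
        p <- cls_preds[[ord[k]]]
        g <- cls_gts[[p$img]]
        best <- 0; best_j <- 0
        for (j in seq_along(g)) {
          if (matched[[p$img]][j]) next
          v <- box_iou(p$box, g[[j]])
          if (v >= thr && v > best) { best <- v; best_j <- j }
        }
        if (best_j > 0) { tp[k] <- 1; matched[[p$img]][best_j] <- TRUE } else fp[k] <- 1
      }
      rec <- cumsum(tp) / n_gt
      prec <- cumsum(tp) / (cumsum(tp) + cumsum(fp))
      env <- rev(cummax(rev(prec)))
      ap[ci, ti] <- sum(diff(c(0, rec)) * env)
    }
  }
  present <- !apply(ap, 1, function(r) all(is.na(r)))
  structure(list(
    map50 = mean(ap[present, 1]),
    map50_95 = mean(ap[present, , drop = FALSE]),
    per_class_ap = ap), class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("mAP@0.5 = %.4f, mAP@0.5:0.95 = %.4f\n", x$map50, x$map50_95))
  invisible(x)
}
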