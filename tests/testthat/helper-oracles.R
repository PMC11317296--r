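# Independent brute-force oracles shared by module and acceptance tests.

# AP oracle: recompute the precision-recall point at every confidence
# cutoff from scratch, then integrate the precision envelope.
ap_oracle <- function(preds, gts, cls, thr) {
  gt_list <- lapply(gts, function(g) Filter(function(b) b$roi_class == cls, g))
  n_gt <- sum(lengths(gt_list))
  pred_list <- list()
  for (i in seq_along(preds))
    for (b in preds[[i]]) if (b$roi_class == cls)
      pred_list[[length(pred_list) + 1]] <- list(img = i, box = b)
  if (n_gt == 0) return(NA_real_)
  if (length(pred_list) == 0) return(0)
  match_count <- function(sel) {
    matched <- lapply(gt_list, function(g) rep(FALSE, length(g)))
    tp <- 0
    for (p in sel) {
      g <- gt_list[[p$img]]
      best <- 0; bj <- 0
      for (j in seq_along(g)) {
        if (matched[[p$img]][j]) next
        v <- box_iou(p$box, g[[j]])
        if (v >= thr && v > best) { best <- v; bj <- j }
      }
      if (bj > 0) { matched[[p$img]][bj] <- TRUE; tp <- tp + 1 }
    }
    tp
  }
  confs <- vapply(pred_list, function(p) p$box$confidence, numeric(1))
  rs <- ps <- numeric(0)
  for (c0 in sort(unique(confs), decreasing = TRUE)) {
    sel <- pred_list[confs >= c0]
    sel <- sel[order(-vapply(sel, function(p) p$box$confidence, numeric(1)))]
    tp <- match_count(sel)
    rs <- c(rs, tp / n_gt); ps <- c(ps, tp / length(sel))
  }
  ap <- 0; prev_r <- 0
  for (k in seq_along(rs)) {
    ap <- ap + (rs[k] - prev_r) * max(ps[k:length(ps)])
    prev_r <- rs[k]
  }
  ap
}

random_toy_set <- function(seed) {
  withr::with_seed(seed, {
    n_img <- sample(1:3, 1)
    gts <- preds <- vector("list", n_img)
    for (i in seq_len(n_img)) {
      gts[[i]] <- lapply(seq_len(sample(0:2, 1)), function(k) {
        x0 <- sample(0:60, 1); y0 <- sample(0:60, 1)
        bounding_box("AL", x0, y0, x0 + sample(10:30, 1), y0 + sample(10:30, 1))
      })
      preds[[i]] <- lapply(seq_len(sample(0:3, 1)), function(k) {
        x0 <- sample(0:60, 1); y0 <- sample(0:60, 1)
        bounding_box("AL", x0, y0, x0 + sample(10:30, 1), y0 + sample(10:30, 1),
                     confidence = round(runif(1), 3))
      })
    }
    while (sum(lengths(gts)) == 0) {
      gts[[1]] <- list(bounding_box("AL", 1, 1, 20, 20))
    }
    list(preds = preds, gts = gts)
  })
}
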