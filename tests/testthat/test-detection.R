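# detection: IoU, coverage, mAP, detector training and inference

test_that("box IoU satisfies its algebra", {
  a <- bounding_box("AL", 0, 0, 10, 10)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, bounding_box("AL", 20, 20, 30, 30)), 0)
  b <- bounding_box("AL", 5, 0, 15, 10)
  expect_equal(box_iou(a, b), 1 / 3)      # 50 / 150
  expect_equal(box_iou(b, a), 1 / 3)      # symmetry
})

test_that("coverage success demands full containment", {
  mask <- matrix(FALSE, 20, 20)
  mask[5:10, 8:14] <- TRUE
  tight <- bounding_box("AL", 7, 4, 14, 10)   # the mask's tight 0-based box
  expect_true(coverage_success(tight, mask))
  shifted <- bounding_box("AL", 8, 4, 15, 10) # one column excluded
  expect_false(coverage_success(shifted, mask))
  expect_error(coverage_success(tight, matrix(FALSE, 5, 5)), "empty")
})


test_that("evaluate_map hits the exact boundary cases", {
  gts <- list(list(bounding_box("AL", 0, 0, 10, 10),
                   bounding_box("CX", 30, 30, 60, 55)),
              list(bounding_box("MB_CAL", 5, 5, 25, 25)))
  perfect <- lapply(gts, function(g) lapply(g, function(b) {
    b$confidence <- 1; b
  }))
  ev <- evaluate_map(perfect, gts)
  expect_equal(ev$map50, 1)
  expect_equal(ev$map50_95, 1)
  expect_gte(ev$map50, ev$map50_95)
  none <- evaluate_map(list(list(), list()), gts)
  expect_equal(none$map50, 0)
})

test_that("a hand-computed 2-image toy set matches", {
  # one true positive at conf 0.9, one false positive at conf 0.8:
  # PR points (0.5, 1) then (0.5, 0.5) over 2 ground truths -> AP = 0.5
  gts <- list(list(bounding_box("AL", 0, 0, 10, 10)),
              list(bounding_box("AL", 0, 0, 10, 10)))
  preds <- list(list(bounding_box("AL", 0, 0, 10, 10, confidence = 0.9)),
                list(bounding_box("AL", 50, 50, 60, 60, confidence = 0.8)))
  ev <- evaluate_map(preds, gts)
  expect_equal(unname(ev$per_class_ap["AL", "0.50"]), 0.5)
  expect_equal(unname(ev$per_class_ap["AL", "0.50"]),
               ap_oracle(preds, gts, "AL", 0.5))
})

test_that("evaluate_map equals the brute-force oracle on random toy sets", {
  for (seed in 61:75) {
    toy <- random_toy_set(seed)
    ev <- evaluate_map(toy$preds, toy$gts)
    for (thr in c(0.5, 0.75)) {
      expect_equal(unname(ev$per_class_ap["AL", sprintf("%.2f", thr)]),
                   ap_oracle(toy$preds, toy$gts, "AL", thr),
                   tolerance = 1e-12, label = sprintf("seed %d thr %g", seed, thr))
    }
  }
})

test_that("mAP is invariant to image order and confidence rescaling", {
  toy <- random_toy_set(80)
  ev <- evaluate_map(toy$preds, toy$gts)
  perm <- rev(seq_along(toy$preds))
  ev2 <- evaluate_map(toy$preds[perm], toy$gts[perm])
  expect_equal(ev$map50, ev2$map50)
  rescaled <- lapply(toy$preds, function(pl) lapply(pl, function(b) {
    b$confidence <- b$confidence / 2; b
  }))
  ev3 <- evaluate_map(rescaled, toy$gts)
  expect_equal(ev$map50, ev3$map50)
  expect_equal(ev$map50_95, ev3$map50_95)
})

test_that("training rejects invalid sets and is seed-deterministic", {
  expect_error(train_detector(list()), "empty")
  ph <- get_tiny_phantom(1)
  pp <- projection_pair(ph$volume)
  expect_error(train_detector(list(list(projection = pp$max, boxes = list()))),
               "zero boxes")
  bad <- list(list(projection = pp$max,
                   boxes = list(bounding_box("AL", 0, 0, 500, 500))))
  expect_error(train_detector(bad), "outside")

  samples <- detector_samples(lapply(1:3, get_tiny_phantom))
  cfg <- detector_config(epochs = 4, seed = 7)
  m1 <- train_detector(samples, cfg)
  m2 <- train_detector(samples, cfg)
  expect_identical(m1$W, m2$W)
  held <- projection_pair(get_tiny_phantom(6)$volume)
  d1 <- detect_rois_pair(m1, held)
  d2 <- detect_rois_pair(m2, held)
  expect_identical(d1, d2)
})

test_that("an untrained (zero-weight) detector detects nothing", {
  cfg <- detector_config(confidence_threshold = 0.999)
  model <- build_detector(cfg)
  blank <- matrix(0, 96, 96)
  expect_equal(detect_rois(model, blank), list())
  # a corrupted model without weights errors
  broken <- model; broken$W <- NULL
  expect_error(detect_rois(broken, blank), "untrained")
})

test_that("a trained detector finds one CX box and two bilateral AL boxes", {
  model <- get_tiny_detector()
  ph <- get_tiny_phantom(9)          # held out from detector training
  det <- detect_rois_pair(model, projection_pair(ph$volume))
  cx <- Filter(function(b) b$roi_class == "CX", det)
  expect_length(cx, 1)
  cx_gt <- Filter(function(b) b$roi_class == "CX", ph$boxes)[[1]]
  expect_true(coverage_success(cx[[1]], component_projection(ph, cx_gt)))
  al <- Filter(function(b) b$roi_class == "AL", det)
  expect_length(al, 2)
  mid <- ph$midline_x
  expect_equal(sum(vapply(al, function(b) (b$x0 + b$x1) / 2 < mid, logical(1))), 1)
})

test_that("held-out detections reach high mAP and full coverage (scaled down)", {
  model <- get_tiny_detector()
  test_ph <- lapply(9:12, get_tiny_phantom)
  preds <- gts <- list(); cover <- logical(0)
  for (ph in test_ph) {
    det <- detect_rois_pair(model, projection_pair(ph$volume))
    preds[[length(preds) + 1]] <- det
    gts[[length(gts) + 1]] <- ph$boxes
    for (gb in ph$boxes) {
      cand <- Filter(function(b) b$roi_class == gb$roi_class, det)
      ok <- length(cand) > 0 &&
        coverage_success(cand[[which.max(vapply(cand, function(b)
          box_iou(b, gb), numeric(1)))]], component_projection(ph, gb))
      cover <- c(cover, ok)
    }
  }
  ev <- evaluate_map(preds, gts)
  expect_gte(ev$map50, 0.9)
  expect_gte(mean(cover), 0.95)
})
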