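# segmentation losses: Dice, weighted Dice, categorical focal, total

test_that("dice loss satisfies its boundary cases and count form", {
  g <- c(1, 1, 0, 0, 1)
  expect_equal(dice_loss(g, g), 0)                       # identity
  expect_equal(dice_loss(g, 1 - g), 1)                   # disjoint
  expect_equal(dice_loss(numeric(4), numeric(4)), 0)     # both empty
  # TP=2, FP=1, FN=1 -> 1 - 4/6 = 1/3
  expect_equal(dice_loss_counts(2, 1, 1), 1 / 3)
  gt <- c(1, 1, 1, 0, 0)
  pr <- c(1, 1, 0, 1, 0)
  expect_equal(dice_loss(gt, pr), 1 / 3)
  expect_equal(dice_loss_counts(0, 0, 0), 0)
})

test_that("count-form and soft-form dice agree on hard predictions", {
  withr::with_seed(21, for (i in 1:5) {
    gt <- rbinom(60, 1, 0.4)
    pr <- rbinom(60, 1, 0.4)
    tp <- sum(gt & pr); fp <- sum(!gt & pr); fn <- sum(gt & !pr)
    expect_equal(dice_loss(gt, pr), dice_loss_counts(tp, fp, fn))
  })
})

test_that("weighted dice follows the printed two-class grouping", {
  # perfect prediction
  expect_equal(weighted_dice_loss(confusion_counts(c(5, 3), c(0, 0), c(0, 0), c(3, 5))), 0)
  # all-zero counts
  expect_equal(weighted_dice_loss(confusion_counts(c(0, 0), c(0, 0), c(0, 0), c(0, 0))), 0)
  # hand evaluation: w = (0.4, 0.6), TP1=10, TP2=2, FN1=FP1=0, FN2=FP2=2
  # S = 5.2, denominator = 10.4 + 1.2 + 1.2 = 12.8 -> 1 - 10.4/12.8 = 0.1875
  cc <- confusion_counts(tp = c(10, 2), fp = c(0, 2), fn = c(0, 2), tn = c(2, 10))
  expect_equal(weighted_dice_loss(cc, c(0.4, 0.6)), 0.1875)
})

test_that("equal weights reduce weighted dice to the pooled dice loss", {
  withr::with_seed(22, for (i in 1:6) {
    tp <- sample(0:20, 2); fp <- sample(0:10, 2); fn <- sample(0:10, 2)
    if (sum(tp, fp, fn) == 0) next
    cc <- confusion_counts(tp, fp, fn, c(0, 0))
    pooled <- dice_loss_counts(sum(tp), sum(fp), sum(fn))
    expect_equal(weighted_dice_loss(cc, c(0.5, 0.5)), pooled)
    expect_equal(weighted_dice_loss(cc, c(2, 2)), pooled)  # scale-invariant
  })
  # explicit example: TP1=TP2=2, FP=FN=1 per class
  cc <- confusion_counts(c(2, 2), c(1, 1), c(1, 1), c(0, 0))
  expect_equal(weighted_dice_loss(cc, c(0.5, 0.5)), dice_loss_counts(4, 2, 2))
})

test_that("focal loss reduces to cross-entropy at gamma 0, alpha 1", {
  withr::with_seed(23, {
    n <- 40
    g <- rbinom(n, 1, 0.5)
    G <- cbind(1 - g, g)
    p <- runif(n, 0.05, 0.95)
    P <- cbind(1 - p, p)
    ce <- -mean(g * log(p) + (1 - g) * log(1 - p))
    expect_equal(categorical_focal_loss(G, P, alpha = c(1, 1), gamma = 0), ce,
                 tolerance = 1e-9)
  })
  # single-voxel plug-ins: p_t = 0.5
  G1 <- matrix(c(0, 1), 1)
  P1 <- matrix(c(0.5, 0.5), 1)
  expect_equal(categorical_focal_loss(G1, P1, c(1, 1), 0), -log(0.5))
  # gamma = 2 multiplies by (1 - 0.5)^2 = 0.25, alpha scales linearly
  expect_equal(categorical_focal_loss(G1, P1, c(0.25, 0.75), 2),
               0.25 * 0.75 * -log(0.5))
  # confident correct prediction: loss -> 0
  expect_lt(categorical_focal_loss(G1, matrix(c(1e-9, 1 - 1e-9), 1), c(1, 1), 2), 1e-6)
})

test_that("total loss is linear in lambda and matches its components", {
  withr::with_seed(24, {
    g <- rbinom(80, 1, 0.3)
    p <- runif(80, 0.02, 0.98)
    P <- cbind(1 - p, p)
    l0 <- total_loss(g, P, loss_config(lambda_mix = 0))
    l1 <- total_loss(g, P, loss_config(lambda_mix = 1))
    l2 <- total_loss(g, P, loss_config(lambda_mix = 2))
    fl <- categorical_focal_loss(cbind(1 - g, g), P, c(0.25, 0.75), 2)
    wd <- weighted_dice_loss(neuropilseg:::soft_confusion(cbind(1 - g, g), P),
                             c(0.4, 0.6))
    expect_equal(l0, wd)
    expect_equal(l1 - l0, fl)
    expect_equal(l2 - l1, fl)
    # perfect hard prediction: total loss ~ 0
    expect_lt(total_loss(g, cbind(1 - g, g), loss_config()), 1e-5)
  })
})

test_that("analytic total-loss gradients match numerical differentiation", {
  withr::with_seed(25, {
    n <- 30
    g <- rbinom(n, 1, 0.4)
    G <- cbind(1 - g, g)
    P <- matrix(runif(2 * n, 0.05, 0.95), n, 2)
    P <- P / rowSums(P)
    cfg <- loss_config()
    an <- neuropilseg:::total_loss_grad(G, P, cfg)
    h <- 1e-6
    for (k in sample(2 * n, 8)) {
      Pp <- P; Pp[k] <- Pp[k] + h
      Pm <- P; Pm[k] <- Pm[k] - h
      num <- (total_loss(G, Pp, cfg) - total_loss(G, Pm, cfg)) / (2 * h)
      expect_equal(an[k], num, tolerance = 1e-4)
    }
  })
})

test_that("textbook dice toggle gives the per-class weighted mean", {
  cc <- confusion_counts(c(10, 2), c(0, 2), c(0, 2), c(2, 10))
  per_class <- c(dice_loss_counts(10, 0, 0), dice_loss_counts(2, 2, 2))
  expect_equal(weighted_dice_loss(cc, c(0.4, 0.6), textbook = TRUE),
               sum(c(0.4, 0.6) * per_class) / 1)
})
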