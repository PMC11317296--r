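# Stage-2 segmentation model: a compact 3D encoder-decoder over
# 64 x 128 x 128 cubes with residual blocks, average-pool downscaling,
# nearest-neighbour upsampling, skip connections and a per-voxel 2-class
# softmax head, trained with Adam under the weighted-Dice + focal
# composite loss.
#
# Desk-scale layout: the first pooling round is a fixed feature pooling of
# the intensity cube (mean, max and smoothed-mean channels at half
# resolution); all learnable layers are pointwise (1x1x1) channel-mixing
# convolutions whose spatial context comes from the pool/upsample pyramid.
# A guided full-resolution head adds an intensity-detail correction
# (amplitude fitted after training) to the upsampled neuropil logit, which
# restores boundary sharpness at a fraction of the cost of full-resolution
# convolutions.  This preserves the architecture contract (residual
# encoder, mirrored decoder with skips, `pooling_rounds` down/up steps,
# softmax voxel head) at CPU-trainable cost.

#' Segmentation model configuration
#'
#' @param pooling_rounds number of pooling/upsampling rounds (default 3 at
#'   desk scale; 5 matches the full-scale layout).  The cube shape must be
#'   divisible by `2^pooling_rounds`.
#' @param base_channels channels of the pointwise layers (desk default 8).
#' @param encoder_blocks integer vector: residual blocks per encoder level
#'   (defaults to 1 per level).
#' @param batch_size cubes per optimization step (default 2).
#' @param epochs training epochs (default 10).
#' @param learning_rate Adam step size.  Desk default 0.01; the full-scale
#'   reference value is 1e-4 (see [paper_seg_config()]).
#' @param val_fraction fraction of brains held out as the validation set
#'   for checkpoint selection (default 0.1, split at the brain level).
#' @param grad_clip global gradient-norm clip (default 5).
#' @param seed RNG seed (initialization and shuffling).
#' @return An object of class `seg_model_config`.
#' @export
seg_model_config <- function(pooling_rounds = 3, base_channels = 8,
                             encoder_blocks = NULL, batch_size = 2,
                             epochs = 10, learning_rate = 0.01,
                             val_fraction = 0.1, grad_clip = 5, seed = 0) {
  assert_that(pooling_rounds >= 1, "pooling_rounds must be >= 1")
  assert_that(all(CUBE_SHAPE %% 2^pooling_rounds == 0),
              "cube shape %s not divisible by 2^%d",
              paste(CUBE_SHAPE, collapse = "x"), pooling_rounds)
  encoder_blocks <- encoder_blocks %||% rep(1L, pooling_rounds)
  assert_that(length(encoder_blocks) == pooling_rounds && all(encoder_blocks >= 1),
              "encoder_blocks must give >= 1 block per level")
  assert_that(batch_size >= 1 && epochs >= 1, "batch_size and epochs must be >= 1")
  assert_that(val_fraction > 0 && val_fraction < 1, "val_fraction must be in (0,1)")
  structure(list(pooling_rounds = pooling_rounds, base_channels = base_channels,
                 encoder_blocks = as.integer(encoder_blocks),
                 batch_size = batch_size, epochs = epochs,
                 learning_rate = learning_rate, val_fraction = val_fraction,
                 grad_clip = grad_clip, seed = seed),
            class = "seg_model_config")
}

#' Full-scale reference configuration
#'
#' Five pooling rounds and the reference learning rate 1e-4; suitable for
#' GPU-scale training, not for the desk-scale test budget.
#' @return A [seg_model_config()].
#' @export
paper_seg_config <- function() {
  seg_model_config(pooling_rounds = 5, base_channels = 16,
                   learning_rate = 1e-4)
}

level_dims <- function(l) as.integer(CUBE_SHAPE / 2^l)

# ---- matrix <-> volume plumbing (per-cube blocks inside a batch) --------

# apply a (Z,Y,X)-array op to every channel of every cube block of a
# stacked (b*n x C) matrix
map_blocks <- function(M, dims, b, fun, out_scale = NULL) {
  n_in <- prod(dims)
  d_out <- fun(array(0, dims))
  n_out <- prod(dim(d_out))
  out <- matrix(0, b * n_out, ncol(M))
  for (i in seq_len(b)) {
    rows_in <- (i - 1) * n_in + seq_len(n_in)
    rows_out <- (i - 1) * n_out + seq_len(n_out)
    for (ch in seq_len(ncol(M))) {
      a <- array(M[rows_in, ch], dims)
      out[rows_out, ch] <- fun(a)
    }
  }
  out
}

pool_mat <- function(M, dims, b) map_blocks(M, dims, b, pool2_avg)
up_mat <- function(M, dims, b) map_blocks(M, dims, b, upsample2)
# adjoints
pool_adj_mat <- function(G, dims_coarse, b) map_blocks(G, dims_coarse, b, upsample2) / 8
up_adj_mat <- function(G, dims_fine, b) map_blocks(G, dims_fine, b, pool2_sum)

relu <- function(x) { x[x < 0] <- 0; x }

# ---- model construction --------------------------------------------------

he_init <- function(n_in, n_out) matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)

new_res_block <- function(C) list(W1 = he_init(C, C), b1 = numeric(C),
                                  W2 = he_init(C, C), b2 = numeric(C))

#' Build an (untrained) segmentation model
#'
#' Residual encoder with `pooling_rounds` levels, mirrored decoder with
#' skip connections, and a softmax voxel head whose full-resolution output
#' has shape `input x 2` classes with per-voxel probabilities summing to 1.
#' The first level is a fixed pooled-feature stem (one pointwise lift);
#' residual blocks sit at the coarser levels, where almost all of the
#' receptive-field growth happens and compute is cheap.
#'
#' @param cfg a [seg_model_config()].
#' @param loss_cfg a [loss_config()] (stored for training).
#' @return An object of class `segmenter_model`.
#' @export
build_segmenter <- function(cfg = seg_model_config(), loss_cfg = loss_config()) {
  C <- cfg$base_channels
  P <- cfg$pooling_rounds
  with_seed(derive_seed(cfg$seed, 11), {
    w <- list(Win = he_init(3, C), bin = numeric(C),
              Wh = he_init(C, 2), bh = numeric(2))
    # encoder residual blocks at levels 2..P (slot 1 is the fixed stem)
    w$enc <- lapply(seq_len(P), function(l) {
      if (l == 1) list() else
        lapply(seq_len(cfg$encoder_blocks[l]), function(k) new_res_block(C))
    })
    if (P >= 2) {
      # merge at levels 1..P-1; decoder residual blocks at levels 2..P-1
      w$mer <- lapply(seq_len(P - 1), function(l)
        list(Wm = he_init(2 * C, C), bm = numeric(C)))
      w$dec <- lapply(seq_len(P - 1), function(l) {
        if (l == 1) list() else list(new_res_block(C))
      })
    } else {
      w$mer <- list(); w$dec <- list()
    }
    structure(list(cfg = cfg, loss_cfg = loss_cfg, w = w, alpha = 0,
                   fitted = FALSE, history = NULL),
              class = "segmenter_model")
  })
}

#' @export
print.segmenter_model <- function(x, ...) {
  cat(sprintf("<segmenter: %d pooling rounds, %d channels, %s>\n",
              x$cfg$pooling_rounds, x$cfg$base_channels,
              if (x$fitted) sprintf("fitted (best val loss %.4f)",
                                    min(x$history$val_loss)) else "untrained"))
  invisible(x)
}

# fixed half-resolution input features of one cube + full-res detail signal
cube_features <- function(arr, with_detail = TRUE) {
  I <- arr / 255
  a <- pool2_avg(I)
  mx <- pool2_max(I)
  s <- smooth_box3(a)
  list(X1 = cbind(as.vector(a), as.vector(mx), as.vector(s)),
       detail = if (with_detail) as.vector(I) - as.vector(upsample2(a)) else NULL)
}

res_fwd <- function(H, p) {
  pre1 <- sweep(H %*% p$W1, 2, p$b1, `+`)
  B1 <- relu(pre1)
  pre2 <- H + sweep(B1 %*% p$W2, 2, p$b2, `+`)
  list(out = relu(pre2), H = H, B1 = B1, m1 = pre1 > 0, m2 = pre2 > 0)
}

res_bwd <- function(dout, cache, p) {
  d2 <- dout * cache$m2
  dW2 <- crossprod(cache$B1, d2)
  db2 <- colSums(d2)
  d1 <- (d2 %*% t(p$W2)) * cache$m1
  dW1 <- crossprod(cache$H, d1)
  db1 <- colSums(d1)
  list(dH = d2 + d1 %*% t(p$W1),
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# forward pass over a stacked batch of b cubes; returns half-res logits
# and (for training) the cache needed for backprop
seg_forward <- function(w, X1, b, P, keep_cache = TRUE) {
  cache <- if (keep_cache) list(X1 = X1) else NULL
  pre_in <- sweep(X1 %*% w$Win, 2, w$bin, `+`)
  A <- relu(pre_in)
  if (keep_cache) cache$min <- pre_in > 0
  E <- vector("list", P); ecache <- vector("list", P)
  H <- A
  for (l in seq_len(P)) {
    if (l > 1) H <- pool_mat(H, level_dims(l - 1), b)
    bl <- vector("list", length(w$enc[[l]]))
    for (k in seq_along(w$enc[[l]])) {
      bl[[k]] <- res_fwd(H, w$enc[[l]][[k]])
      H <- bl[[k]]$out
      if (!keep_cache) bl[[k]] <- NULL
    }
    E[[l]] <- H; ecache[[l]] <- bl
  }
  if (keep_cache) { cache$ecache <- ecache; cache$E <- E }
  D <- E[[P]]
  mcache <- dcache <- vector("list", max(P - 1, 0))
  if (P >= 2) for (l in (P - 1):1) {
    U <- up_mat(D, level_dims(l + 1), b)
    CC <- cbind(U, E[[l]])
    preM <- sweep(CC %*% w$mer[[l]]$Wm, 2, w$mer[[l]]$bm, `+`)
    M <- relu(preM)
    if (keep_cache) mcache[[l]] <- list(CC = CC, mm = preM > 0)
    E[l] <- list(NULL)        # allow reclamation in inference mode
    bl <- vector("list", length(w$dec[[l]]))
    H <- M
    for (k in seq_along(w$dec[[l]])) {
      bl[[k]] <- res_fwd(H, w$dec[[l]][[k]])
      H <- bl[[k]]$out
      if (!keep_cache) bl[[k]] <- NULL
    }
    dcache[[l]] <- bl
    D <- H
  }
  if (keep_cache) { cache$mcache <- mcache; cache$dcache <- dcache }
  logits <- sweep(D %*% w$Wh, 2, w$bh, `+`)
  if (keep_cache) cache$D <- D
  list(logits = logits, cache = cache)
}

seg_backward <- function(w, dlogits, cache, b, P) {
  g <- list(Win = NULL, bin = NULL, Wh = crossprod(cache$D, dlogits),
            bh = colSums(dlogits))
  g$enc <- rapply(w$enc, function(x) x * 0, how = "replace")
  g$mer <- rapply(w$mer, function(x) x * 0, how = "replace")
  g$dec <- rapply(w$dec, function(x) x * 0, how = "replace")
  dD <- dlogits %*% t(w$Wh)
  dE <- vector("list", P)          # skip-connection gradients
  for (l in seq_len(max(P - 1, 0))) dE[[l]] <- 0
  if (P >= 2) for (l in seq_len(P - 1)) {
    for (k in rev(seq_along(w$dec[[l]]))) {
      r <- res_bwd(dD, cache$dcache[[l]][[k]], w$dec[[l]][[k]])
      g$dec[[l]][[k]] <- r$grads
      dD <- r$dH
    }
    mc <- cache$mcache[[l]]
    dpre <- dD * mc$mm
    g$mer[[l]]$Wm <- crossprod(mc$CC, dpre)
    g$mer[[l]]$bm <- colSums(dpre)
    dCC <- dpre %*% t(w$mer[[l]]$Wm)
    C <- ncol(w$Win)
    dU <- dCC[, seq_len(C), drop = FALSE]
    dE[[l]] <- dE[[l]] + dCC[, C + seq_len(C), drop = FALSE]
    dD <- up_adj_mat(dU, level_dims(l), b)     # gradient into D_{l+1}
  }
  # encoder backward, deepest level first; dD currently holds dE[[P]]
  dH <- dD
  for (l in rev(seq_len(P))) {
    if (l < P) dH <- dH + dE[[l]]
    for (k in rev(seq_along(w$enc[[l]]))) {
      r <- res_bwd(dH, cache$ecache[[l]][[k]], w$enc[[l]][[k]])
      g$enc[[l]][[k]] <- r$grads
      dH <- r$dH
    }
    if (l > 1) dH <- pool_adj_mat(dH, level_dims(l), b)
  }
  dpre <- dH * cache$min
  g$Win <- crossprod(cache$X1, dpre)
  g$bin <- colSums(dpre)
  g
}

# flatten/unflatten parameter lists for the Adam update
flatten_params <- function(w) unlist(w, use.names = FALSE)
unflatten_params <- function(w, v) {
  relist_into <- function(x) {
    if (is.list(x)) return(lapply(x, relist_into))
    n <- length(x)
    out <- v[pos:(pos + n - 1)]
    pos <<- pos + n
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }
  pos <- 1
  relist_into(w)
}

softmax2 <- function(logits) {
  # numerically stable two-class softmax
  d <- logits[, 2] - logits[, 1]
  p <- 1 / (1 + exp(-d))
  cbind(1 - p, p)
}

#' Train the stage-2 segmenter
#'
#' Minimizes the composite weighted-Dice + focal loss with Adam; one
#' independent model should be trained per structure.  The validation set
#' is split at the brain level (`source_id`), and whenever a lower
#' validation loss is observed at an epoch end the model state is
#' checkpointed; the returned model carries the best checkpoint, not the
#' final epoch.  After the main loop the guided-refinement amplitude of
#' the full-resolution head is calibrated on validation cubes.
#'
#' @param cubes list of `cube_window`s with masks (from
#'   [build_training_cubes()]).
#' @param cfg a [seg_model_config()].
#' @param loss_cfg a [loss_config()].
#' @param quiet suppress per-epoch progress.
#' @return A fitted `segmenter_model` with a `history` data.frame
#'   (epoch, train_loss, val_loss); deterministic given `cfg$seed`.
#' @export
train_segmenter <- function(cubes, cfg = seg_model_config(),
                            loss_cfg = loss_config(), quiet = TRUE) {
  assert_that(length(cubes) >= 2, "need at least 2 cubes")
  assert_that(!loss_cfg$textbook_dice,
              "training gradients are implemented for the pooled weighted-Dice grouping")
  model <- build_segmenter(cfg, loss_cfg)
  P <- cfg$pooling_rounds
  n1 <- prod(level_dims(1))

  # brain-level validation split (fallback: cube-level when single-brain)
  ids <- vapply(cubes, function(cb) cb$source_id, character(1))
  uids <- unique(ids)
  val_idx <- with_seed(derive_seed(cfg$seed, 21), {
    if (length(uids) > 1) {
      n_val <- max(1, round(cfg$val_fraction * length(uids)))
      vids <- sample(uids, n_val)
      which(ids %in% vids)
    } else {
      sample(seq_along(cubes), max(1, round(cfg$val_fraction * length(cubes))))
    }
  })
  train_idx <- setdiff(seq_along(cubes), val_idx)
  assert_that(length(train_idx) >= 1, "validation split consumed every cube")

  # cache half-res features and pooled soft labels once
  feat <- vector("list", length(cubes))
  lab <- vector("list", length(cubes))
  for (i in seq_along(cubes)) {
    f <- cube_features(cube_data(cubes[[i]]))
    m <- cube_mask(cubes[[i]])
    assert_that(!is.null(m), "cube %d has no mask", i)
    fr <- as.vector(pool2_avg(m * 1))
    feat[[i]] <- f$X1
    lab[[i]] <- cbind(1 - fr, fr)
  }

  w <- model$w
  flat <- flatten_params(w)
  mom <- vel <- numeric(length(flat))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  best_val <- Inf; best_w <- w
  hist_train <- hist_val <- numeric(cfg$epochs)

  eval_loss <- function(w, idx) {
    mean(vapply(idx, function(i) {
      fw <- seg_forward(w, feat[[i]], 1, P, keep_cache = FALSE)
      total_loss(lab[[i]], softmax2(fw$logits), loss_cfg)
    }, numeric(1)))
  }

  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 100 + ep), sample(train_idx))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      nb <- length(bt)
      X <- do.call(rbind, feat[bt])
      G <- do.call(rbind, lab[bt])
      fw <- seg_forward(w, X, nb, P)
      Pm <- softmax2(fw$logits)
      lval <- total_loss(G, Pm, loss_cfg)
      if (!is.finite(lval))
        stopf("NaN/Inf loss at epoch %d; try a smaller learning rate", ep)
      ep_loss <- ep_loss + lval * nb
      dP <- total_loss_grad(G, Pm, loss_cfg)
      dlogits <- Pm * (dP - rowSums(dP * Pm))
      grads <- seg_backward(w, dlogits, fw$cache, nb, P)
      gflat <- flatten_params(grads)
      gn <- sqrt(sum(gflat^2))
      if (gn > cfg$grad_clip) gflat <- gflat * cfg$grad_clip / gn
      t <- t + 1
      mom <- b1 * mom + (1 - b1) * gflat
      vel <- b2 * vel + (1 - b2) * gflat^2
      flat <- flatten_params(w) -
        cfg$learning_rate * (mom / (1 - b1^t)) / (sqrt(vel / (1 - b2^t)) + eps)
      w <- unflatten_params(w, flat)
    }
    hist_train[ep] <- ep_loss / length(train_idx)
    hist_val[ep] <- eval_loss(w, val_idx)
    if (!quiet)
      message(sprintf("epoch %d: train %.4f  val %.4f", ep, hist_train[ep], hist_val[ep]))
    if (hist_val[ep] < best_val) { best_val <- hist_val[ep]; best_w <- w }
  }
  model$w <- best_w
  model$history <- data.frame(epoch = seq_len(cfg$epochs),
                              train_loss = hist_train, val_loss = hist_val)
  model$fitted <- TRUE

  # calibrate the guided full-resolution refinement amplitude on up to 4
  # validation cubes (only the neuropil logit is corrected)
  calib_idx <- val_idx[seq_len(min(4, length(val_idx)))]
  calib <- lapply(calib_idx, function(i) {
    arr <- cube_data(cubes[[i]])
    f <- cube_features(arr)
    fw <- seg_forward(best_w, f$X1, 1, P, keep_cache = FALSE)
    up <- map_blocks(fw$logits, level_dims(1), 1, upsample2)
    list(up = up, detail = f$detail, g = as.numeric(cube_mask(cubes[[i]]) > 0))
  })
  obj <- function(a) {
    mean(vapply(calib, function(cc) {
      lg <- cc$up
      lg[, 2] <- lg[, 2] + a * cc$detail
      total_loss(cc$g, softmax2(lg), loss_cfg)
    }, numeric(1)))
  }
  model$alpha <- stats::optimize(obj, c(0, 60), tol = 0.5)$minimum
  if (obj(0) <= obj(model$alpha)) model$alpha <- 0
  model
}

#' Per-voxel class probabilities for one cube
#'
#' @param model a fitted `segmenter_model`.
#' @param cube_arr 64 x 128 x 128 intensity array (or a `cube_window`).
#' @param refine apply the guided full-resolution correction (default
#'   `TRUE`); `FALSE` upsamples the half-resolution probabilities directly
#'   (faster, blockier — adequate for volume screening).
#' @return 64 x 128 x 128 x 2 probability array, rows summing to 1.
#' @export
predict_cube <- function(model, cube_arr, refine = TRUE) {
  assert_that(inherits(model, "segmenter_model") && model$fitted,
              "untrained model: train_segmenter() first")
  if (inherits(cube_arr, "cube_window")) cube_arr <- cube_data(cube_arr)
  assert_that(identical(dim(cube_arr), as.integer(CUBE_SHAPE)),
              "cube must be %s", paste(CUBE_SHAPE, collapse = "x"))
  f <- cube_features(cube_arr, with_detail = refine)
  fw <- seg_forward(model$w, f$X1, 1, model$cfg$pooling_rounds,
                    keep_cache = FALSE)
  lg <- map_blocks(fw$logits, level_dims(1), 1, upsample2)
  if (refine) lg[, 2] <- lg[, 2] + model$alpha * f$detail
  pr <- softmax2(lg)
  array(pr, c(CUBE_SHAPE, 2))
}

#' Segment a standardized ROI
#'
#' Sliding-window inference: predicts every window and stitches the
#' per-cube probabilities by mean fusion.
#'
#' @param model a fitted `segmenter_model`.
#' @param roi a [standardize_roi()] result.
#' @param stride inference stride (default 20; coarser strides that still
#'   tile the ROI, e.g. `c(60, 40, 40)`, trade seam smoothness for speed).
#' @param mirror also average Z-mirrored predictions.
#' @param refine see [predict_cube()].
#' @return 124 x 168 x 168 x 2 probability array.
#' @export
predict_roi <- function(model, roi, stride = DEFAULT_STRIDE, mirror = FALSE,
                        refine = TRUE) {
  assert_that(inherits(model, "segmenter_model") && model$fitted,
              "untrained model: train_segmenter() first")
  cubes <- sliding_windows(roi, stride = stride, mirror = mirror)
  P <- model$cfg$pooling_rounds
  n1 <- prod(level_dims(1))
  out <- vector("list", length(cubes))
  # batch the network forward over chunks of cubes (bounds memory while
  # amortizing the per-operation overhead)
  chunks <- split(seq_along(cubes), ceiling(seq_along(cubes) / 8))
  for (ch in chunks) {
    feats <- lapply(cubes[ch], function(cb)
      cube_features(cube_data(cb), with_detail = refine))
    fw <- seg_forward(model$w, do.call(rbind, lapply(feats, `[[`, "X1")),
                      length(ch), P, keep_cache = FALSE)
    for (j in seq_along(ch)) {
      lg1 <- fw$logits[(j - 1) * n1 + seq_len(n1), , drop = FALSE]
      pr <- if (refine) {
        lg <- map_blocks(lg1, level_dims(1), 1, upsample2)
        lg[, 2] <- lg[, 2] + model$alpha * feats[[j]]$detail
        softmax2(lg)
      } else {
        # softmax commutes with nearest upsampling: do it at half res
        map_blocks(softmax2(lg1), level_dims(1), 1, upsample2)
      }
      cb <- cubes[[ch[j]]]
      out[[ch[j]]] <- list(offset = cb$offset, mirrored = cb$mirrored,
                           probs = array(pr, c(CUBE_SHAPE, 2)))
    }
  }
  stitch(out)
}

#' Segment one structure of a full volume
#'
#' Composes the ROI pipeline end to end for each of the structure's boxes
#' (two for a bilateral structure) and unions the restored masks.
#'
#' @param model a fitted `segmenter_model`.
#' @param vol a [volume_stack()].
#' @param boxes list of [bounding_box()] for the structure.
#' @param margin_frac,stride,refine pipeline parameters.
#' @return A binary [label_volume()] aligned with `vol`.
#' @export
segment_structure <- function(model, vol, boxes, margin_frac = 0.05,
                              stride = DEFAULT_STRIDE, refine = TRUE) {
  assert_that(length(boxes) >= 1, "no boxes supplied")
  d <- dim(vol$data)
  out <- array(0L, d)
  for (b in boxes) {
    roi <- box_to_roi3d(b, vol, margin_frac)
    std <- standardize_roi(roi)
    pr <- predict_roi(model, std, stride = stride, refine = refine)
    lv <- restore(pr, std$geometry, d)
    out <- pmax(out, lv$data)
  }
  label_volume(out, classes = c("background", "neuropil"))
}
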