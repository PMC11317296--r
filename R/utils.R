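# Internal array helpers shared across modules.  All volumes use axis order
# (Z, Y, X); all coordinates are 0-based with half-open intervals.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

#' @keywords internal
is_wholenumber <- function(x, tol = 1e-8) all(abs(x - round(x)) < tol)

# ---- 2D resampling -------------------------------------------------------

# Bilinear resize of a (H, W) matrix to (out_h, out_w).  Uses the
# pixel-center alignment convention: source coordinate of output pixel i is
# (i + 0.5) * H / out_h - 0.5 (0-based), clamped to the image.
resize_bilinear <- function(mat, out_h, out_w) {
  h <- nrow(mat); w <- ncol(mat)
  if (h == out_h && w == out_w) return(mat)
  sy <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  sx <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  sy <- pmin(pmax(sy, 0), h - 1)
  sx <- pmin(pmax(sx, 0), w - 1)
  y0 <- pmin(floor(sy), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(floor(sx), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- sy - y0; fx <- sx - x0
  a <- mat[y0 + 1, x0 + 1, drop = FALSE]
  b <- mat[y1 + 1, x0 + 1, drop = FALSE]
  cc <- mat[y0 + 1, x1 + 1, drop = FALSE]
  d <- mat[y1 + 1, x1 + 1, drop = FALSE]
  top <- a * (1 - fy) + b * fy
  bot <- cc * (1 - fy) + d * fy
  sweep(top, 2, 1 - fx, `*`) + sweep(bot, 2, fx, `*`)
}

# Nearest-neighbour resize of a (H, W) matrix (used for label planes).
resize_nearest <- function(mat, out_h, out_w) {
  h <- nrow(mat); w <- ncol(mat)
  if (h == out_h && w == out_w) return(mat)
  sy <- pmin(pmax(floor((seq_len(out_h) - 0.5) * h / out_h), 0), h - 1)
  sx <- pmin(pmax(floor((seq_len(out_w) - 0.5) * w / out_w), 0), w - 1)
  mat[sy + 1, sx + 1, drop = FALSE]
}

# ---- 3D helpers ----------------------------------------------------------

# Resample every Z-slice of a (Z,Y,X) array in XY.
resize_volume_xy <- function(arr, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  out <- array(0, dim = c(d[1], out_h, out_w))
  f <- if (method == "bilinear") resize_bilinear else resize_nearest
  for (z in seq_len(d[1])) out[z, , ] <- f(matrix(arr[z, , ], d[2], d[3]), out_h, out_w)
  out
}

flip_z <- function(arr) {
  d <- dim(arr)
  arr[rev(seq_len(d[1])), , , drop = FALSE]
}

# Separable 3x3x3 box smoothing with zero padding at the edges.  The kernel
# is symmetric, so the operator is self-adjoint (relevant for gradients).
smooth_box3 <- function(arr) {
  d <- dim(arr)
  sm_axis <- function(a, ax) {
    n <- dim(a)[ax]
    if (n < 2) return(a)
    lo <- hi <- a
    idx <- function(i) switch(ax,
      a[i, , , drop = FALSE], a[, i, , drop = FALSE], a[, , i, drop = FALSE])
    z <- switch(ax,
      array(0, c(1, d[2], d[3])), array(0, c(d[1], 1, d[3])), array(0, c(d[1], d[2], 1)))
    lo <- abind_axis(z, idx(seq_len(n - 1)), ax)
    hi <- abind_axis(idx(seq(2, n)), z, ax)
    (lo + a + hi) / 3
  }
  for (ax in 1:3) arr <- sm_axis(arr, ax)
  arr
}

# Minimal binding of two arrays along one axis (avoids an abind dependency).
abind_axis <- function(a, b, ax) {
  da <- dim(a); db <- dim(b)
  dd <- da; dd[ax] <- da[ax] + db[ax]
  out <- array(0, dd)
  ia <- lapply(seq_along(dd), function(i) seq_len(da[i]))
  ib <- lapply(seq_along(dd), function(i) seq_len(db[i]))
  ib[[ax]] <- da[ax] + seq_len(db[ax])
  do.call(`[<-`, c(list(out), ia, list(a))) -> out
  do.call(`[<-`, c(list(out), ib, list(b))) -> out
  out
}

# 2x2x2 average pooling of a (Z,Y,X) array with even dims, via strided adds.
pool2_avg <- function(arr) {
  d <- dim(arr)
  assert_that(all(d %% 2 == 0), "pool2_avg needs even dims, got %s", paste(d, collapse = "x"))
  a <- arr[seq(1, d[1], 2), , , drop = FALSE] + arr[seq(2, d[1], 2), , , drop = FALSE]
  a <- a[, seq(1, d[2], 2), , drop = FALSE] + a[, seq(2, d[2], 2), , drop = FALSE]
  a <- a[, , seq(1, d[3], 2), drop = FALSE] + a[, , seq(2, d[3], 2), drop = FALSE]
  a / 8
}

# 2x2x2 max pooling (used only for fixed input features, never backpropped).
pool2_max <- function(arr) {
  d <- dim(arr)
  a <- pmax(arr[seq(1, d[1], 2), , , drop = FALSE], arr[seq(2, d[1], 2), , , drop = FALSE])
  a <- pmax(a[, seq(1, d[2], 2), , drop = FALSE], a[, seq(2, d[2], 2), , drop = FALSE])
  pmax(a[, , seq(1, d[3], 2), drop = FALSE], a[, , seq(2, d[3], 2), drop = FALSE])
}

# Nearest 2x upsampling of a (Z,Y,X) array.
upsample2 <- function(arr) {
  d <- dim(arr)
  arr[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
      rep(seq_len(d[3]), each = 2), drop = FALSE]
}

# Adjoint of upsample2: 2x2x2 sum pooling.
pool2_sum <- function(arr) pool2_avg(arr) * 8

clip01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
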