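# Z-axis projections: collapse a 3D stack into the 2D images that feed the
# stage-1 detector.  Two modes are used so the detector sees both peak and
# integrated brightness: per-pixel maximum along Z, and per-pixel mean along
# Z min-max rescaled to 8-bit (summation and mean are identical after the
# rescale, which resolves the sum-vs-average naming inconsistency).

#' Project a volume along Z
#'
#' @param vol a [volume_stack()].
#' @param mode `"max"` (per-pixel maximum over Z) or `"mean"` (per-pixel
#'   mean over Z, then min-max rescaled to [0, 255]; a constant stack has
#'   degenerate range and maps to 0).
#' @return An object of class `projection2d`: `data` (Y, X matrix in
#'   [0, 255]), `mode`, `source_id`.
#' @export
project <- function(vol, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  assert_that(inherits(vol, "volume_stack"), "vol must be a volume_stack")
  arr <- vol$data
  d <- dim(arr)
  assert_that(prod(d) > 0, "empty volume")
  img <- if (mode == "max") {
    out <- matrix(arr[1, , ], d[2], d[3])
    if (d[1] > 1) for (z in 2:d[1]) out <- pmax(out, matrix(arr[z, , ], d[2], d[3]))
    out
  } else {
    m <- colMeans(arr, dims = 1)          # (Y, X) mean over Z
    rng <- range(m)
    if (rng[2] > rng[1]) round((m - rng[1]) / (rng[2] - rng[1]) * 255) else m * 0
  }
  structure(list(data = img, mode = mode, source_id = vol$source_id),
            class = "projection2d")
}

#' @export
print.projection2d <- function(x, ...) {
  cat(sprintf("<projection2d %s [%s]: %d x %d>\n", x$source_id, x$mode,
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Both Z-projections of a volume
#'
#' @param vol a [volume_stack()].
#' @return Named list with elements `max` and `mean`, each a `projection2d`.
#' @export
projection_pair <- function(vol) {
  list(max = project(vol, "max"), mean = project(vol, "mean"))
}
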