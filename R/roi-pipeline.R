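# From a detected 2D box to standardized 3D ROIs, sliding-window cubes for
# training/inference, and stitching of cube predictions back into the
# original volume geometry.
#
# Standardized ROI geometry: Z zero-padded to 124 layers (extra layer at
# the far end when the padding is odd), XY resampled to 168 x 168.
# Cubes are 64 x 128 x 128 windows placed at every multiple of the stride
# (default 20): 4 x 3 x 3 = 36 placements, 72 with Z-mirroring, hence 144
# per bilateral structure and brain, and 2304 for 16 brains.

ROI_SHAPE <- c(124L, 168L, 168L)
CUBE_SHAPE <- c(64L, 128L, 128L)
DEFAULT_STRIDE <- 20L

#' Extract the 3D region behind a 2D box
#'
#' The box constrains XY only (detection happens on Z-projections); the
#' region spans the full stack depth.  The box is dilated by `margin_frac`
#' of its width/height per side, then clipped to the image.
#'
#' @param box a [bounding_box()] on the volume's Z-projection.
#' @param vol a [volume_stack()].
#' @param margin_frac fractional dilation per side (default 0.05, insuring
#'   full neuropil coverage against tight boxes).
#' @return An object of class `roi3d`: `data` (Z, Y, X subarray), 0-based
#'   half-open `yrange`/`xrange` in the source volume, `box`, `source_id`.
#' @export
box_to_roi3d <- function(box, vol, margin_frac = 0.05) {
  assert_that(inherits(box, "bounding_box"), "box must be a bounding_box")
  assert_that(inherits(vol, "volume_stack"), "vol must be a volume_stack")
  d <- dim(vol$data)
  mw <- round(margin_frac * (box$x1 - box$x0))
  mh <- round(margin_frac * (box$y1 - box$y0))
  x0 <- max(0, box$x0 - mw); x1 <- min(d[3], box$x1 + mw)
  y0 <- max(0, box$y0 - mh); y1 <- min(d[2], box$y1 + mh)
  assert_that(x1 > x0 && y1 > y0, "degenerate box after clipping")
  structure(list(data = vol$data[, (y0 + 1):y1, (x0 + 1):x1, drop = FALSE],
                 yrange = c(y0, y1), xrange = c(x0, x1),
                 box = box, source_id = vol$source_id),
            class = "roi3d")
}

#' Standardize an ROI to the fixed model geometry
#'
#' Zero-pads Z symmetrically to 124 layers (odd padding puts the extra
#' layer at the far end) and resamples XY to 168 x 168 (bilinear for
#' intensities, nearest for masks).  The recorded geometry is sufficient to
#' invert the transform with [restore()].
#'
#' @param roi an `roi3d` from [box_to_roi3d()], or a bare (Z, Y, X) array.
#' @param mask optional aligned binary mask array (same shape as the ROI
#'   data).
#' @return An object of class `standardized_roi`: `data`
#'   (124 x 168 x 168), `mask` (or `NULL`), `geometry`, `source_id`.
#' @export
standardize_roi <- function(roi, mask = NULL) {
  arr <- if (inherits(roi, "roi3d")) roi$data else roi
  assert_that(is.array(arr) && length(dim(arr)) == 3, "roi must be a 3D array or roi3d")
  d <- dim(arr)
  assert_that(d[1] <= ROI_SHAPE[1],
              "region Z = %d exceeds the standardized depth %d; deeper stacks are rejected",
              d[1], ROI_SHAPE[1])
  if (!is.null(mask)) assert_that(identical(dim(mask), d), "mask shape must match roi")
  pad_lo <- (ROI_SHAPE[1] - d[1]) %/% 2
  pad_hi <- ROI_SHAPE[1] - d[1] - pad_lo
  std <- array(0, ROI_SHAPE)
  std[pad_lo + seq_len(d[1]), , ] <-
    resize_volume_xy(arr, ROI_SHAPE[2], ROI_SHAPE[3], "bilinear")
  std_mask <- NULL
  if (!is.null(mask)) {
    std_mask <- array(0L, ROI_SHAPE)
    std_mask[pad_lo + seq_len(d[1]), , ] <-
      resize_volume_xy(mask, ROI_SHAPE[2], ROI_SHAPE[3], "nearest")
  }
  geometry <- list(orig_dim = d, pad_lo = pad_lo, pad_hi = pad_hi,
                   yrange = if (inherits(roi, "roi3d")) roi$yrange else c(0, d[2]),
                   xrange = if (inherits(roi, "roi3d")) roi$xrange else c(0, d[3]))
  structure(list(data = std, mask = std_mask, geometry = geometry,
                 source_id = if (inherits(roi, "roi3d")) roi$source_id else ""),
            class = "standardized_roi")
}

#' Sliding-window cubes over a standardized ROI
#'
#' Windows of 64 x 128 x 128 are placed at every multiple of the stride at
#' which they fit; (124 - 64) and (168 - 128) must be divisible by the
#' stride.  At the default stride 20 this yields 4 x 3 x 3 = 36 cubes, or
#' 72 with Z-mirrored copies appended.  Cubes are lightweight views
#' (offset + reference); materialize voxels with [cube_data()] /
#' [cube_mask()].
#'
#' @param roi a [standardize_roi()] result.
#' @param stride sliding distance in voxels (scalar or per-axis length 3).
#' @param mirror append a Z-flipped copy of every cube.
#' @return List of `cube_window` objects with fields `offset` (0-based
#'   (z, y, x)), `mirrored`, `roi`, `source_id`.
#' @export
sliding_windows <- function(roi, stride = DEFAULT_STRIDE, mirror = FALSE) {
  assert_that(inherits(roi, "standardized_roi"), "roi must be a standardized_roi")
  s <- rep_len(as.integer(stride), 3)
  span <- ROI_SHAPE - CUBE_SHAPE
  assert_that(all(span %% s == 0),
              "window span %s not divisible by stride %s",
              paste(span, collapse = ","), paste(s, collapse = ","))
  offs <- lapply(1:3, function(ax) seq(0L, span[ax], by = s[ax]))
  cubes <- list()
  for (oz in offs[[1]]) for (oy in offs[[2]]) for (ox in offs[[3]]) {
    cubes[[length(cubes) + 1]] <- structure(
      list(offset = c(oz, oy, ox), mirrored = FALSE, roi = roi,
           source_id = roi$source_id),
      class = "cube_window")
  }
  if (mirror) {
    n <- length(cubes)
    for (i in seq_len(n)) {
      cb <- cubes[[i]]
      cb$mirrored <- TRUE
      cubes[[n + i]] <- cb
    }
  }
  cubes
}

#' Materialize the intensity window of a cube
#' @param cube a `cube_window`.
#' @return 64 x 128 x 128 numeric array (Z-flipped if the cube is mirrored).
#' @export
cube_data <- function(cube) {
  o <- cube$offset
  w <- cube$roi$data[o[1] + seq_len(CUBE_SHAPE[1]),
                     o[2] + seq_len(CUBE_SHAPE[2]),
                     o[3] + seq_len(CUBE_SHAPE[3]), drop = FALSE]
  if (cube$mirrored) flip_z(w) else w
}

#' Materialize the label window of a cube
#' @param cube a `cube_window` whose ROI carries a mask.
#' @return 64 x 128 x 128 integer array, or `NULL` if the ROI has no mask.
#' @export
cube_mask <- function(cube) {
  if (is.null(cube$roi$mask)) return(NULL)
  o <- cube$offset
  w <- cube$roi$mask[o[1] + seq_len(CUBE_SHAPE[1]),
                     o[2] + seq_len(CUBE_SHAPE[2]),
                     o[3] + seq_len(CUBE_SHAPE[3]), drop = FALSE]
  if (cube$mirrored) flip_z(w) else w
}

#' Expected cube counts from the augmentation arithmetic
#'
#' @param n_brains number of brains.
#' @param laterality `"bilateral"` (2 ROIs per brain) or `"midline"` (1).
#' @param stride sliding distance.
#' @param mirror whether Z-mirrored copies are counted.
#' @return Integer cube count (e.g. 16 bilateral brains at stride 20 with
#'   mirroring give 2304).
#' @export
count_training_cubes <- function(n_brains, laterality = c("bilateral", "midline"),
                                 stride = DEFAULT_STRIDE, mirror = TRUE) {
  laterality <- match.arg(laterality)
  s <- rep_len(as.integer(stride), 3)
  span <- ROI_SHAPE - CUBE_SHAPE
  assert_that(all(span %% s == 0), "span not divisible by stride")
  per_roi <- prod(span %/% s + 1L) * (if (mirror) 2L else 1L)
  n_brains * per_roi * (if (laterality == "bilateral") 2L else 1L)
}

#' Build the training cube set for one structure
#'
#' For every brain, each of the structure's ROIs (2 for bilateral
#' structures, 1 for midline) is extracted behind its box, standardized
#' with its mask, and expanded into mirrored sliding-window cubes.
#'
#' @param brains list of brains; each a list with `volume`
#'   ([volume_stack()]), `masks` (named list of binary [label_volume()] per
#'   class), `boxes` (list of [bounding_box()]).  [generate_phantom()]
#'   output is accepted directly.
#' @param structure ROI class name (`"AL"`, `"MB_CAL"`, `"CX"`).
#' @param margin_frac box dilation for [box_to_roi3d()].
#' @param stride,mirror see [sliding_windows()].
#' @return Flat list of `cube_window` objects.
#' @export
build_training_cubes <- function(brains, structure, margin_frac = 0.05,
                                 stride = DEFAULT_STRIDE, mirror = TRUE) {
  assert_that(length(brains) >= 1, "empty brain list")
  cubes <- list()
  for (br in brains) {
    bx <- Filter(function(b) b$roi_class == structure, br$boxes)
    assert_that(length(bx) >= 1, "brain %s has no box for structure %s",
                br$volume$source_id %||% "?", structure)
    mask_arr <- br$masks[[structure]]$data
    assert_that(!is.null(mask_arr), "brain is missing a mask for %s", structure)
    for (b in bx) {
      roi <- box_to_roi3d(b, br$volume, margin_frac)
      m <- mask_arr[, (roi$yrange[1] + 1):roi$yrange[2],
                    (roi$xrange[1] + 1):roi$xrange[2], drop = FALSE]
      std <- standardize_roi(roi, mask = m)
      cubes <- c(cubes, sliding_windows(std, stride = stride, mirror = mirror))
    }
  }
  cubes
}

#' Stitch cube probabilities back into ROI space
#'
#' Per-voxel mean of class probabilities over all covering cubes; mirrored
#' cubes are un-flipped first.  Every ROI voxel must be covered by at least
#' one cube (the 36-placement tiling guarantees this).
#'
#' @param cube_probs list of entries `list(offset =, mirrored =, probs =)`
#'   where `probs` is a 64 x 128 x 128 x 2 array.
#' @return 124 x 168 x 168 x 2 probability array whose per-voxel class
#'   probabilities sum to 1.
#' @export
stitch <- function(cube_probs) {
  assert_that(length(cube_probs) >= 1, "no cubes to stitch")
  acc <- array(0, c(ROI_SHAPE, 2))
  cnt <- array(0, ROI_SHAPE)
  for (cp in cube_probs) {
    p <- cp$probs
    assert_that(identical(dim(p)[1:3], as.integer(CUBE_SHAPE)) && dim(p)[4] == 2,
                "cube probs must be %s x 2", paste(CUBE_SHAPE, collapse = "x"))
    if (isTRUE(cp$mirrored)) p <- p[rev(seq_len(dim(p)[1])), , , , drop = FALSE]
    o <- cp$offset
    zr <- o[1] + seq_len(CUBE_SHAPE[1])
    yr <- o[2] + seq_len(CUBE_SHAPE[2])
    xr <- o[3] + seq_len(CUBE_SHAPE[3])
    acc[zr, yr, xr, ] <- acc[zr, yr, xr, ] + p
    cnt[zr, yr, xr] <- cnt[zr, yr, xr] + 1
  }
  assert_that(all(cnt > 0), "some ROI voxels are covered by no cube")
  acc[, , , 1] <- acc[, , , 1] / cnt
  acc[, , , 2] <- acc[, , , 2] / cnt
  acc
}

#' Restore ROI-space predictions to the original volume
#'
#' Takes the per-voxel argmax (ties resolve to background), strips the Z
#' padding, resamples XY back to the original ROI size
#' (nearest-neighbour), and places the labels into a zero background of the
#' full volume shape.
#'
#' @param prob_vol 124 x 168 x 168 x 2 probability array (or a
#'   124 x 168 x 168 label array).
#' @param geometry the `geometry` of the [standardize_roi()] that produced
#'   the ROI.
#' @param vol_shape (Z, Y, X) of the original full volume.
#' @return A binary [label_volume()] of shape `vol_shape`.
#' @export
restore <- function(prob_vol, geometry, vol_shape) {
  nd <- length(dim(prob_vol))
  labels <- if (nd == 4) {
    assert_that(identical(dim(prob_vol)[1:3], as.integer(ROI_SHAPE)),
                "prob volume must be %s x 2", paste(ROI_SHAPE, collapse = "x"))
    # strict > : an exact 0.5/0.5 tie stays background
    array(as.integer(prob_vol[, , , 2] > prob_vol[, , , 1]), ROI_SHAPE)
  } else {
    assert_that(identical(dim(prob_vol), as.integer(ROI_SHAPE)),
                "label volume must be %s", paste(ROI_SHAPE, collapse = "x"))
    prob_vol
  }
  d <- geometry$orig_dim
  assert_that(d[1] == vol_shape[1],
              "geometry Z extent (%d) does not match volume shape Z (%d)", d[1], vol_shape[1])
  core <- labels[geometry$pad_lo + seq_len(d[1]), , , drop = FALSE]
  back <- resize_volume_xy(core, d[2], d[3], "nearest")
  out <- array(0L, vol_shape)
  out[seq_len(d[1]),
      (geometry$yrange[1] + 1):geometry$yrange[2],
      (geometry$xrange[1] + 1):geometry$xrange[2]] <- as.integer(back > 0)
  out <- label_volume(out, classes = c("background", "neuropil"))
  out
}
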