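# 2D bounding boxes on Z-projections and their text annotation format.
#
# The file dialect is the normalized-center detector format: one box per
# line, `class_index cx cy w h [confidence]`, all geometry normalized to
# [0, 1].  Class indices map 0 -> AL, 1 -> MB_CAL, 2 -> CX.  In memory,
# boxes are 0-based half-open pixel rectangles [x0, x1) x [y0, y1).

#' Construct a 2D bounding box
#'
#' @param roi_class one of `"AL"`, `"MB_CAL"`, `"CX"` (antennal lobe,
#'   mushroom body + calyx, central complex).
#' @param x0,y0,x1,y1 pixel coordinates, 0-based, half-open.
#' @param confidence detection confidence in [0, 1].
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(roi_class, x0, y0, x1, y1, confidence = 1) {
  assert_that(roi_class %in% ROI_CLASSES,
              "roi_class must be one of %s", paste(ROI_CLASSES, collapse = ", "))
  assert_that(x0 < x1 && y0 < y1, "need x0 < x1 and y0 < y1 (got %g,%g,%g,%g)",
              x0, y0, x1, y1)
  assert_that(confidence >= 0 && confidence <= 1, "confidence must be in [0,1]")
  structure(list(roi_class = roi_class, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                 confidence = confidence),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<box %s [%g,%g)x[%g,%g) conf %.3f>\n",
              x$roi_class, x$x0, x$x1, x$y0, x$y1, x$confidence))
  invisible(x)
}

box_area <- function(b) (b$x1 - b$x0) * (b$y1 - b$y0)

clip_box <- function(b, image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  x0 <- max(0, min(b$x0, w)); x1 <- max(0, min(b$x1, w))
  y0 <- max(0, min(b$y0, h)); y1 <- max(0, min(b$y1, h))
  assert_that(x0 < x1 && y0 < y1, "box degenerate after clipping to %dx%d", h, w)
  bounding_box(b$roi_class, x0, y0, x1, y1, b$confidence)
}

#' Read box annotations (normalized-center text format)
#'
#' @param path text file with one box per line:
#'   `class_index cx cy w h [confidence]`, all in [0, 1].
#' @param image_shape integer (H, W) of the projection the boxes refer to.
#' @return List of [bounding_box()] denormalized to 0-based half-open pixel
#'   coordinates (rounded to whole pixels and clipped to the image).
#' @export
read_boxes <- function(path, image_shape) {
  assert_that(file.exists(path), "file not found: %s", path)
  assert_that(length(image_shape) == 2 && all(image_shape >= 1),
              "image_shape must be (H, W)")
  h <- image_shape[1]; w <- image_shape[2]
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  boxes <- list()
  for (i in seq_along(lines)) {
    f <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
    if (length(f) < 5 || length(f) > 6 || anyNA(f))
      stopf("malformed box line %d in %s: '%s'", i, path, lines[i])
    cls_idx <- f[1]
    assert_that(is_wholenumber(cls_idx) && cls_idx >= 0 && cls_idx <= 2,
                "class index out of range on line %d in %s", i, path)
    assert_that(all(f[2:5] >= 0) && all(f[2:5] <= 1),
                "normalized value outside [0,1] on line %d in %s", i, path)
    conf <- if (length(f) == 6) f[6] else 1
    cx <- f[2] * w; cy <- f[3] * h; bw <- f[4] * w; bh <- f[5] * h
    x0 <- round(cx - bw / 2); x1 <- round(cx + bw / 2)
    y0 <- round(cy - bh / 2); y1 <- round(cy + bh / 2)
    x0 <- max(0, x0); y0 <- max(0, y0); x1 <- min(w, x1); y1 <- min(h, y1)
    boxes[[i]] <- bounding_box(ROI_CLASSES[cls_idx + 1], x0, y0, x1, y1, conf)
  }
  boxes
}

#' Write box annotations (normalized-center text format)
#'
#' Inverse of [read_boxes()]; the round trip agrees within one pixel
#' (quantization of the normalized representation).
#'
#' @param boxes list of [bounding_box()].
#' @param image_shape integer (H, W).
#' @param path output path.
#' @export
write_boxes <- function(boxes, image_shape, path) {
  assert_that(length(image_shape) == 2 && all(image_shape >= 1),
              "image_shape must be (H, W) with positive entries")
  h <- image_shape[1]; w <- image_shape[2]
  lines <- vapply(boxes, function(b) {
    cls <- match(b$roi_class, ROI_CLASSES) - 1
    sprintf("%d %.6f %.6f %.6f %.6f %.6f", cls,
            (b$x0 + b$x1) / 2 / w, (b$y0 + b$y1) / 2 / h,
            (b$x1 - b$x0) / w, (b$y1 - b$y0) / h, b$confidence)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
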