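# Volume containers and multi-page TIFF I/O.
#
# The on-disk format is baseline TIFF: uncompressed, single-channel,
# 8-bit (or 16-bit on read, with explicit rescale), one page per Z-slice.
# Only this dialect is supported; it is what the rest of the package writes,
# and it keeps the stacks portable across tifffile/ImageJ-style tooling.

ROI_CLASSES <- c("AL", "MB_CAL", "CX")

#' Construct a 3D intensity volume
#'
#' A `volume_stack` holds a 3D intensity array in (Z, Y, X) axis order with
#' 8-bit semantics (values in 0..255) and physical voxel-size metadata.
#'
#' @param data numeric 3D array, axis order (Z, Y, X), values in [0, 255].
#' @param voxel_size numeric length-3, physical size (dx, dy, dz) of one
#'   voxel in micrometres.  The reference imaging geometry is
#'   0.32 x 0.32 x 1 um.
#' @param source_id character identifier for the sample.
#' @return An object of class `volume_stack` with elements `data`,
#'   `voxel_size`, `source_id`.
#' @export
volume_stack <- function(data, voxel_size = c(0.32, 0.32, 1), source_id = "") {
  assert_that(is.array(data) && length(dim(data)) == 3, "volume data must be a 3D array")
  assert_that(all(dim(data) >= 1), "all dims must be >= 1")
  rng <- range(data)
  assert_that(rng[1] >= 0 && rng[2] <= 255, "intensities must lie in [0, 255]")
  assert_that(length(voxel_size) == 3 && all(voxel_size > 0),
              "voxel_size must be 3 strictly positive numbers")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 source_id = as.character(source_id)),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_stack %s: %d x %d x %d (Z,Y,X), voxel %s um>\n",
              x$source_id, d[1], d[2], d[3], paste(x$voxel_size, collapse = " x ")))
  invisible(x)
}

#' Construct a voxel-wise label volume
#'
#' @param data integer 3D array (Z, Y, X); every voxel is a class index into
#'   `classes` (0-based, 0 = background).
#' @param classes ordered character vector of class names; index 0 is
#'   background.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, classes = c("background", "neuropil")) {
  assert_that(is.array(data) && length(dim(data)) == 3, "label data must be a 3D array")
  assert_that(is_wholenumber(range(data)), "labels must be integers")
  assert_that(min(data) >= 0 && max(data) <= length(classes) - 1,
              "voxel values must be valid class indices (0..%d)", length(classes) - 1)
  structure(list(data = data, classes = as.character(classes)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_volume %d x %d x %d, classes: %s>\n",
              d[1], d[2], d[3], paste(x$classes, collapse = ", ")))
  invisible(x)
}

# ---- TIFF primitives -----------------------------------------------------

tiff_type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8)

read_tiff_pages <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  assert_that(length(raw) >= 8, "not a TIFF file (too short): %s", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stopf("not a TIFF file (bad byte order mark): %s", path))
  rd <- function(off, n, size, signed = TRUE) {
    # readBin only honours signed for sizes 1 and 2; 4-byte reads are
    # signed, which is safe for offsets below 2 GiB
    readBin(raw[(off + 1):(off + n * size)], "integer", n = n, size = size,
            signed = signed || size >= 4, endian = endian)
  }
  magic <- rd(2, 1, 2, signed = FALSE)
  assert_that(magic == 42, "not a TIFF file (bad magic): %s", path)
  ifd_off <- rd(4, 1, 4)
  pages <- list()
  description <- NULL
  while (ifd_off != 0) {
    n_entries <- rd(ifd_off, 1, 2, signed = FALSE)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- rd(e, 1, 2, signed = FALSE)
      typ <- rd(e + 2, 1, 2, signed = FALSE)
      cnt <- rd(e + 4, 1, 4)
      sz <- tiff_type_size[as.character(typ)]
      if (is.na(sz)) next
      total <- sz * cnt
      voff <- if (total <= 4) e + 8 else rd(e + 8, 1, 4)
      vals <- if (typ == 2) {
        chars <- raw[(voff + 1):(voff + cnt)]
        rawToChar(chars[chars != as.raw(0)])
      } else if (typ == 5) {
        num <- rd(voff, 2 * cnt, 4)
        num[seq(1, 2 * cnt, 2)] / num[seq(2, 2 * cnt, 2)]
      } else {
        rd(voff, cnt, sz, signed = FALSE)
      }
      tags[[as.character(tag)]] <- vals
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    bits <- tags[["258"]] %||% 1
    comp <- tags[["259"]] %||% 1
    assert_that(!is.null(w) && !is.null(h), "TIFF page missing dimensions: %s", path)
    assert_that(all(comp == 1), "only uncompressed TIFF is supported: %s", path)
    assert_that(all(bits %in% c(8, 16)) && length(bits) == 1,
                "only 8- or 16-bit single-channel TIFF is supported: %s", path)
    spp <- tags[["277"]] %||% 1
    assert_that(all(spp == 1), "multi-sample (color) TIFF is not supported: %s", path)
    offs <- tags[["273"]]; counts <- tags[["279"]]
    assert_that(!is.null(offs) && !is.null(counts), "TIFF page missing strip layout: %s", path)
    bpp <- bits / 8
    vals <- integer(w * h)
    pos <- 1
    for (s in seq_along(offs)) {
      n_px <- counts[s] / bpp
      vals[pos:(pos + n_px - 1)] <-
        readBin(raw[(offs[s] + 1):(offs[s] + counts[s])], "integer",
                n = n_px, size = bpp, signed = FALSE, endian = endian)
      pos <- pos + n_px
    }
    if (is.null(description)) description <- tags[["270"]]
    # TIFF is row-major: first w values are the top row
    pages[[length(pages) + 1]] <- list(mat = t(matrix(vals, nrow = w, ncol = h)),
                                       bits = bits)
    ifd_off <- rd(ifd_off + 2 + n_entries * 12, 1, 4)
  }
  list(pages = pages, description = description)
}

#' Read a multi-page TIFF stack as a volume
#'
#' Pages map to ascending Z.  Data deeper than 8 bits are rejected unless
#' `rescale = TRUE`, in which case they are min-max mapped to [0, 255].
#'
#' @param path path to an uncompressed single-channel multi-page TIFF.
#' @param rescale logical; allow >8-bit input via min-max rescaling.
#' @param voxel_size optional voxel size override; when absent, a
#'   `voxel_size=dx,dy,dz` entry in the TIFF ImageDescription is honoured,
#'   falling back to the reference geometry 0.32 x 0.32 x 1 um.
#' @return A [volume_stack()].
#' @export
read_volume <- function(path, rescale = FALSE, voxel_size = NULL) {
  parsed <- read_tiff_pages(path)
  pages <- parsed$pages
  assert_that(length(pages) >= 1, "TIFF has no pages: %s", path)
  dims <- vapply(pages, function(p) dim(p$mat), integer(2))
  assert_that(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
              "inconsistent page dimensions in %s", path)
  bits <- unique(vapply(pages, function(p) p$bits, numeric(1)))
  assert_that(length(bits) == 1, "mixed bit depths in %s", path)
  if (bits > 8 && !rescale)
    stopf(">8-bit data in %s; pass rescale = TRUE to min-max map to [0,255]", path)
  arr <- array(0, dim = c(length(pages), dims[1, 1], dims[2, 1]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]$mat
  if (bits > 8) {
    rng <- range(arr)
    arr <- if (rng[2] > rng[1]) round((arr - rng[1]) / (rng[2] - rng[1]) * 255) else arr * 0
  }
  if (is.null(voxel_size)) {
    voxel_size <- c(0.32, 0.32, 1)
    desc <- parsed$description
    if (!is.null(desc) && grepl("voxel_size=", desc)) {
      v <- suppressWarnings(as.numeric(strsplit(sub(".*voxel_size=", "", desc), ",")[[1]]))
      if (length(v) == 3 && !anyNA(v) && all(v > 0)) voxel_size <- v
    }
  }
  volume_stack(arr, voxel_size = voxel_size,
               source_id = sub("\\.tiff?$", "", basename(path)))
}

#' Write a volume as an uncompressed 8-bit multi-page TIFF
#'
#' Round-trips bit-exactly through [read_volume()].  Voxel size is stored in
#' the ImageDescription tag.
#'
#' @param vol a [volume_stack()] or [label_volume()] (class indices are
#'   written as 8-bit intensities).
#' @param path output path.
#' @export
write_volume <- function(vol, path) {
  arr <- if (inherits(vol, "label_volume")) vol$data else vol$data
  assert_that(is.array(arr) && length(dim(arr)) == 3, "need a volume_stack or label_volume")
  vs <- if (inherits(vol, "volume_stack")) vol$voxel_size else c(0.32, 0.32, 1)
  d <- dim(arr)
  z <- d[1]; h <- d[2]; w <- d[3]
  desc <- sprintf("voxel_size=%g,%g,%g", vs[1], vs[2], vs[3])
  desc_raw <- c(charToRaw(desc), as.raw(0))
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header
  writeBin(charToRaw("II"), con); wr2(42)
  desc_off <- 8
  data_off <- desc_off + length(desc_raw)
  page_bytes <- h * w
  first_ifd <- data_off + z * page_bytes
  wr4(first_ifd)
  writeBin(desc_raw, con)
  for (k in seq_len(z)) {
    # write row-major: transpose the (Y, X) slice
    writeBin(as.raw(as.integer(t(matrix(arr[k, , ], h, w)))), con)
  }
  n_base <- 9L
  for (k in seq_len(z)) {
    with_desc <- k == 1
    n <- n_base + as.integer(with_desc)
    entry <- function(tag, typ, cnt, val) {
      wr2(tag); wr2(typ); wr4(cnt)
      if (typ == 3) { wr2(val); wr2(0) } else wr4(val)
    }
    wr2(n)
    entry(256, 4, 1, w)
    entry(257, 4, 1, h)
    entry(258, 3, 1, 8)
    entry(259, 3, 1, 1)
    entry(262, 3, 1, 1)
    if (with_desc) entry(270, 2, length(desc_raw), desc_off)
    entry(273, 4, 1, data_off + (k - 1) * page_bytes)
    entry(277, 3, 1, 1)
    entry(278, 4, 1, h)
    entry(279, 4, 1, page_bytes)
    # next-IFD pointer: IFD sizes differ because page 1 carries the
    # description entry, so compute offsets explicitly
    size1 <- 2 + (n_base + 1) * 12 + 4
    sizek <- 2 + n_base * 12 + 4
    next_off <- if (k == z) 0 else first_ifd + size1 + (k - 1) * sizek
    wr4(next_off)
  }
  invisible(path)
}

#' Read a label volume from TIFF
#'
#' @inheritParams read_volume
#' @param classes ordered class names (index 0 = background).
#' @return A [label_volume()].
#' @export
read_labels <- function(path, classes = c("background", "neuropil")) {
  v <- read_volume(path)
  label_volume(v$data, classes = classes)
}
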