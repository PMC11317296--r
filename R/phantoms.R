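# Synthetic phantom brains: textured background plus bilateral and midline
# ellipsoid-composite "neuropils" with known masks, boxes, midline and
# controllable left/right volume asymmetry.  The generator emulates the
# geometry of anti-DLG-style confocal stacks (bright multi-lobed structures
# on a dim noisy background) without claiming anatomical realism.

#' Default phantom structure geometry
#'
#' Three ROI classes mirror the detector's grouping: a bilateral single-lobe
#' structure (AL analog), a bilateral three-lobe structure (mushroom body +
#' calyx analog, the asymmetry target), and a midline two-lobe structure
#' (central complex analog).  Positions are fractions of the (Y, X) extent;
#' radii are voxels at the default 64 x 256 x 256 desk scale.
#'
#' @return Named list of per-class geometry specs.
#' @export
default_phantom_structures <- function() {
  list(
    AL = list(laterality = "bilateral", base_radii = c(9, 13, 13),
              lobe_count = 1, center_y_frac = 0.72, lateral_frac = 0.30,
              intensity = 120),
    MB_CAL = list(laterality = "bilateral", base_radii = c(11, 17, 14),
                  lobe_count = 3, center_y_frac = 0.34, lateral_frac = 0.26,
                  intensity = 150),
    CX = list(laterality = "midline", base_radii = c(8, 11, 19),
              lobe_count = 2, center_y_frac = 0.58, lateral_frac = 0,
              intensity = 135)
  )
}

#' Specify a synthetic phantom brain
#'
#' @param shape integer (Z, Y, X) voxel extent; default 64 x 256 x 256
#'   (desk scale stand-in for 1024 x 1024 XY confocal stacks).
#' @param structures per-class geometry, see [default_phantom_structures()].
#' @param asymmetry signed fractional right-vs-left volume difference
#'   planted in the classes named by `asymmetric_classes`:
#'   (V_R - V_L) / mean(V_L, V_R) = asymmetry, |asymmetry| < 1.
#' @param asymmetric_classes character; bilateral classes that receive the
#'   planted asymmetry (`"all"` = every bilateral class).
#' @param noise_sd additive Gaussian intensity noise (8-bit units).
#' @param background_level background intensity (8-bit units).
#' @param jitter maximum uniform center jitter in voxels (mirror-symmetric
#'   for bilateral structures).
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 256, 256),
                         structures = default_phantom_structures(),
                         asymmetry = 0, asymmetric_classes = "MB_CAL",
                         noise_sd = 8, background_level = 30,
                         jitter = 3, seed = 1) {
  assert_that(length(shape) == 3 && all(shape >= 8), "shape must be (Z,Y,X), each >= 8")
  assert_that(abs(asymmetry) < 1, "|asymmetry| must be < 1")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(shape = as.integer(shape), structures = structures,
                 asymmetry = asymmetry,
                 asymmetric_classes = asymmetric_classes,
                 noise_sd = noise_sd, background_level = background_level,
                 jitter = jitter, seed = seed),
            class = "phantom_spec")
}

# rasterize a union of ellipsoid lobes; returns sorted linear voxel
# indices into a (Z,Y,X) array of the given shape (sparse representation,
# cheap enough for whole-cohort generation)
rasterize_lobes <- function(shape, center, radii) {
  Z <- shape[1]; Y <- shape[2]
  idx <- integer(0)
  for (lb in lobe_layout(center, radii)) {
    c0 <- lb$center; r <- lb$radii
    assert_that(all(c0 - r >= 1) && all(c0 + r <= shape),
                "structure radii exceed the volume (center %s, radii %s)",
                paste(round(c0), collapse = ","), paste(round(r, 1), collapse = ","))
    zr <- floor(c0[1] - r[1]):ceiling(c0[1] + r[1])
    yr <- floor(c0[2] - r[2]):ceiling(c0[2] + r[2])
    xr <- floor(c0[3] - r[3]):ceiling(c0[3] + r[3])
    dz2 <- ((zr - c0[1]) / r[1])^2
    dy2 <- ((yr - c0[2]) / r[2])^2
    dx2 <- ((xr - c0[3]) / r[3])^2
    inside <- which(outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1)
    nz <- length(zr); ny <- length(yr)
    i0 <- inside - 1
    lz <- i0 %% nz; rest <- i0 %/% nz; ly <- rest %% ny; lx <- rest %/% ny
    idx <- c(idx, (xr[lx + 1] - 1) * Z * Y + (yr[ly + 1] - 1) * Z + zr[lz + 1])
  }
  sort(unique(idx))
}

# deterministic multi-lobe layout: main ellipsoid plus smaller lobes offset
# along +/- Y and +Z, scaled with the main radii (so volume scaling applied
# to `radii` scales the whole composite)
lobe_layout <- function(center, radii) {
  lobes <- list(list(center = center, radii = radii))
  n_extra <- attr(radii, "lobe_count") %||% 1
  if (n_extra >= 2) {
    for (k in 2:n_extra) {
      sgn <- if (k %% 2 == 0) -1 else 1
      off <- c(0.35 * radii[1], sgn * 0.95 * radii[2], 0)
      lobes[[k]] <- list(center = center + off, radii = radii * 0.55)
    }
  }
  lobes
}

#' Generate a phantom brain with ground truth
#'
#' Bilateral structures are placed mirror-symmetrically about the midline
#' column, then the right (left) component radii are scaled by
#' (1 + a/2)^(1/3) ((1 - a/2)^(1/3)) so the planted voxel-count asymmetry
#' matches `spec$asymmetry` up to rasterization error (about 1-2 percent).
#' Intensity = background + per-structure boost + Gaussian noise, clipped to
#' [0, 255].  Boxes are tight XY bounding boxes of each component's
#' Z-projection.
#'
#' @param spec a [phantom_spec()].
#' @param keep_volume logical; set `FALSE` to drop the intensity volume
#'   (masks and truth only), useful for large cohorts.
#' @return An object of class `phantom`: `volume` ([volume_stack()] or
#'   `NULL`), `masks` (named list of binary [label_volume()] per class),
#'   `labels` (combined multi-class [label_volume()]), `boxes` (list of
#'   [bounding_box()], one per component), `midline_x` (0-based column of
#'   the sagittal midline), `truth` (data.frame: class, side, voxels), and
#'   the originating `spec`.
#' @export
generate_phantom <- function(spec, keep_volume = TRUE) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  shape <- spec$shape
  Z <- shape[1]; Y <- shape[2]; X <- shape[3]
  midline_x <- X / 2          # 0-based boundary column: x < midline is left
  a <- spec$asymmetry
  s_right <- (1 + a / 2)^(1 / 3)
  s_left <- (1 - a / 2)^(1 / 3)
  asym_classes <- spec$asymmetric_classes
  if (identical(asym_classes, "all"))
    asym_classes <- names(Filter(function(s) s$laterality == "bilateral", spec$structures))

  with_seed(spec$seed, {
    comp <- list()   # per component: list(class, side, idx)
    for (cls in names(spec$structures)) {
      st <- spec$structures[[cls]]
      jit <- round(stats::runif(3, -spec$jitter, spec$jitter))
      cz <- Z / 2 + jit[1]
      cy <- st$center_y_frac * Y + jit[2]
      radii <- st$base_radii
      attr(radii, "lobe_count") <- st$lobe_count
      if (st$laterality == "bilateral") {
        # mirror-symmetric placement about the midline (mirror of 0-based
        # column c is X-1-c; centers here are 1-based, mirror is X+1-c)
        cx_left <- midline_x - st$lateral_frac * X + jit[3] + 1
        cx_right <- X + 1 - cx_left
        sc <- if (cls %in% asym_classes) c(s_left, s_right) else c(1, 1)
        for (i in 1:2) {
          r <- radii * sc[i]
          attr(r, "lobe_count") <- st$lobe_count
          ctr <- c(cz, cy, if (i == 1) cx_left else cx_right)
          comp[[length(comp) + 1]] <-
            list(class = cls, side = c("left", "right")[i],
                 idx = rasterize_lobes(shape, ctr, r))
        }
      } else {
        comp[[length(comp) + 1]] <-
          list(class = cls, side = "midline",
               idx = rasterize_lobes(shape, c(cz, cy, midline_x + 0.5), radii))
      }
    }

    # overlap check across components (sparse index collision)
    all_idx <- unlist(lapply(comp, `[[`, "idx"))
    if (anyDuplicated(all_idx))
      stopf("phantom structures overlap after placement")

    labels <- array(0L, shape)
    masks <- list()
    intensity <- rep(as.numeric(spec$background_level), prod(shape))
    for (cls in names(spec$structures)) {
      cls_idx <- unlist(lapply(Filter(function(cm) cm$class == cls, comp), `[[`, "idx"))
      m <- array(0L, shape)
      m[cls_idx] <- 1L
      masks[[cls]] <- label_volume(m, classes = c("background", cls))
      labels[cls_idx] <- match(cls, ROI_CLASSES)
      intensity[cls_idx] <- spec$background_level + spec$structures[[cls]]$intensity
    }
    if (spec$noise_sd > 0)
      intensity <- intensity + stats::rnorm(length(intensity), 0, spec$noise_sd)
    intensity <- array(round(pmin(pmax(intensity, 0), 255)), shape)

    boxes <- lapply(comp, function(cm) {
      i0 <- cm$idx - 1
      yy <- (i0 %/% Z) %% Y; xx <- i0 %/% (Z * Y)
      bounding_box(cm$class, min(xx), min(yy), max(xx) + 1, max(yy) + 1, 1)
    })
    truth <- data.frame(
      class = vapply(comp, `[[`, "", "class"),
      side = vapply(comp, `[[`, "", "side"),
      voxels = vapply(comp, function(cm) length(cm$idx), numeric(1)),
      stringsAsFactors = FALSE)

    source_id <- sprintf("phantom_seed%d", as.integer(spec$seed))
    structure(list(
      volume = if (keep_volume) volume_stack(intensity, source_id = source_id) else NULL,
      masks = masks,
      labels = label_volume(labels, classes = c("background", ROI_CLASSES)),
      boxes = boxes, midline_x = midline_x, truth = truth, spec = spec,
      source_id = source_id), class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %s: %s voxels, %d boxes, midline x=%g>\n", x$source_id,
              paste(x$spec$shape, collapse = "x"), length(x$boxes), x$midline_x))
  invisible(x)
}

# measured signed percent volume difference of a bilateral class, from the
# emitted truth table (voxel-count oracle)
phantom_percent_diff <- function(ph, class = "MB_CAL") {
  tr <- ph$truth[ph$truth$class == class, ]
  vl <- tr$voxels[tr$side == "left"]; vr <- tr$voxels[tr$side == "right"]
  100 * (vr - vl) / ((vl + vr) / 2)
}

#' Generate a cohort of phantoms
#'
#' @param n number of phantoms (>= 1).
#' @param asymmetry_sampler distribution spec for per-phantom asymmetry:
#'   `list(type = "normal", mean =, sd =)`,
#'   `list(type = "uniform", min =, max =)`, or
#'   `list(type = "fixed", values =)` (recycled to length `n`).
#' @param seed integer seed; the cohort is reproducible given the seed.
#' @param base_spec template [phantom_spec()]; per-phantom seed and
#'   asymmetry are derived from `seed` and the sampler.
#' @param keep_volume keep intensity volumes (memory-heavy for large n).
#' @return List of `n` [generate_phantom()] results.
#' @export
generate_cohort <- function(n, asymmetry_sampler = list(type = "normal", mean = 0, sd = 0.08),
                            seed = 1, base_spec = phantom_spec(),
                            keep_volume = FALSE) {
  assert_that(n >= 1, "n must be >= 1")
  asym <- with_seed(derive_seed(seed, 0), {
    switch(asymmetry_sampler$type,
      normal = stats::rnorm(n, asymmetry_sampler$mean, asymmetry_sampler$sd),
      uniform = stats::runif(n, asymmetry_sampler$min, asymmetry_sampler$max),
      fixed = rep_len(asymmetry_sampler$values, n),
      stopf("unknown asymmetry sampler type '%s'", asymmetry_sampler$type))
  })
  assert_that(all(is.finite(asym)) && all(abs(asym) < 1),
              "sampled asymmetries must be finite with |a| < 1")
  lapply(seq_len(n), function(i) {
    sp <- base_spec
    sp$asymmetry <- asym[i]
    sp$seed <- derive_seed(seed, i)
    ph <- generate_phantom(sp, keep_volume = keep_volume)
    ph$source_id <- sprintf("phantom_%03d", i)
    if (!is.null(ph$volume)) ph$volume$source_id <- ph$source_id
    ph
  })
}
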