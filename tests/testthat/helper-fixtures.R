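# Shared fixtures.  Expensive objects (phantoms, mini trained models) are
# built once per test run and memoized here; everything is generated in
# code under fixed seeds.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# Desk-scale phantom (64 x 256 x 256), memoized by seed/asymmetry.
get_phantom <- function(seed, asymmetry = 0) {
  memo(sprintf("ph_%d_%g", seed, asymmetry),
       generate_phantom(phantom_spec(seed = seed, asymmetry = asymmetry)))
}

# Miniature phantom spec (24 x 96 x 96): same three structures scaled to
# ~40%, for fast I/O, detection and morphometry tests.
tiny_phantom_spec <- function(seed = 1, asymmetry = 0, ...) {
  st <- list(
    AL = list(laterality = "bilateral", base_radii = c(3.5, 5, 5),
              lobe_count = 1, center_y_frac = 0.72, lateral_frac = 0.30,
              intensity = 120),
    MB_CAL = list(laterality = "bilateral", base_radii = c(4.5, 6.5, 5.5),
                  lobe_count = 3, center_y_frac = 0.34, lateral_frac = 0.26,
                  intensity = 150),
    CX = list(laterality = "midline", base_radii = c(3.5, 4.5, 7.5),
              lobe_count = 2, center_y_frac = 0.58, lateral_frac = 0,
              intensity = 135)
  )
  phantom_spec(shape = c(24, 96, 96), structures = st, jitter = 1,
               seed = seed, asymmetry = asymmetry, ...)
}

get_tiny_phantom <- function(seed, asymmetry = 0) {
  memo(sprintf("tph_%d_%g", seed, asymmetry),
       generate_phantom(tiny_phantom_spec(seed = seed, asymmetry = asymmetry)))
}

# Detector samples (both projection modes) from a list of phantoms.
detector_samples <- function(phantoms) {
  out <- list()
  for (ph in phantoms) {
    pp <- projection_pair(ph$volume)
    out[[length(out) + 1]] <- list(projection = pp$max, boxes = ph$boxes)
    out[[length(out) + 1]] <- list(projection = pp$mean, boxes = ph$boxes)
  }
  out
}

# Small trained detector on tiny phantoms (shared across detection tests).
get_tiny_detector <- function() {
  memo("tiny_detector", {
    phs <- lapply(1:8, get_tiny_phantom)
    train_detector(detector_samples(phs), detector_config(epochs = 25, seed = 3))
  })
}

# Mini segmenter: 8 cubes from one desk-scale phantom, 3 epochs.  Quality
# is poor by design; used for contract tests (shapes, determinism,
# checkpointing), not accuracy.
mini_seg_cubes <- function() {
  memo("mini_cubes", {
    ph <- get_phantom(31)
    cubes <- build_training_cubes(list(ph), "MB_CAL")
    cubes[round(seq(1, length(cubes), length.out = 8))]
  })
}

get_mini_segmenter <- function() {
  memo("mini_segmenter", {
    train_segmenter(mini_seg_cubes(),
                    seg_model_config(epochs = 3, seed = 5))
  })
}

# Z-projection (Y, X) of a binary mask volume.
mask_projection <- function(mask) {
  arr <- if (inherits(mask, "label_volume")) mask$data else mask
  colSums(arr, dims = 1) > 0
}

# Restrict a full-class mask projection to one component via its truth box.
component_projection <- function(ph, box) {
  proj <- mask_projection(ph$masks[[box$roi_class]])
  sub <- matrix(FALSE, nrow(proj), ncol(proj))
  sub[(box$y0 + 1):box$y1, (box$x0 + 1):box$x1] <-
    proj[(box$y0 + 1):box$y1, (box$x0 + 1):box$x1]
  sub
}
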