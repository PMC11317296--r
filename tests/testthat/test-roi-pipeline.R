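# roi_pipeline: extraction, standardization, windows, stitch, restore

test_that("box_to_roi3d extracts the dilated, clipped XY region", {
  vol <- volume_stack(array(0, c(6, 64, 64)))
  b <- bounding_box("AL", 10, 10, 50, 50)
  roi <- box_to_roi3d(b, vol, margin_frac = 0)
  expect_equal(dim(roi$data), c(6, 40, 40))
  expect_equal(roi$xrange, c(10, 50)); expect_equal(roi$yrange, c(10, 50))
  # 5% margin on a 40-px box dilates 2 px per side
  roi2 <- box_to_roi3d(b, vol, margin_frac = 0.05)
  expect_equal(roi2$xrange, c(8, 52))
  expect_equal(dim(roi2$data)[2:3], c(44, 44))
  # corner box is clipped at 0
  roi3 <- box_to_roi3d(bounding_box("AL", 0, 0, 20, 20), vol, margin_frac = 0.1)
  expect_equal(roi3$xrange, c(0, 22)); expect_equal(roi3$yrange, c(0, 22))
})

test_that("standardization pads Z and resamples XY as documented", {
  # exact-geometry input is the identity transform
  arr <- array(withr::with_seed(41, runif(124 * 168 * 168, 0, 255)),
               c(124, 168, 168))
  std <- standardize_roi(arr)
  expect_equal(std$data, arr)
  expect_equal(std$geometry$pad_lo, 0)

  # Z = 100 pads 12 zero layers each side
  arr2 <- array(1, c(100, 30, 30))
  std2 <- standardize_roi(arr2)
  expect_equal(std2$geometry$pad_lo, 12)
  expect_true(all(std2$data[1:12, , ] == 0))
  expect_true(all(std2$data[113:124, , ] == 0))
  # odd deficit: extra layer at the far end
  std3 <- standardize_roi(array(1, c(99, 30, 30)))
  expect_equal(std3$geometry$pad_lo, 12)
  expect_equal(std3$geometry$pad_hi, 13)

  # constant input stays constant through the interpolation
  expect_true(all(abs(std2$data[13:112, , ] - 1) < 1e-12))

  expect_error(standardize_roi(array(0, c(130, 10, 10))), "exceeds")
})

test_that("sliding windows realize the augmentation arithmetic", {
  std <- standardize_roi(array(0, c(64, 80, 80)))
  expect_length(sliding_windows(std, mirror = FALSE), 36)   # 4 * 3 * 3
  cubes <- sliding_windows(std, mirror = TRUE)
  expect_length(cubes, 72)
  expect_equal(sum(vapply(cubes, `[[`, logical(1), "mirrored")), 36)
  # offsets lie on the stride lattice and inside the ROI
  for (cb in cubes[c(1, 18, 36, 50)]) {
    expect_true(all(cb$offset %% 20 == 0))
    expect_true(all(cb$offset + c(64, 128, 128) <= c(124, 168, 168)))
  }
  # stride must divide the span
  expect_error(sliding_windows(std, stride = 25), "divisible")
  # per-axis strides giving the minimal 2x2x2 tiling
  expect_length(sliding_windows(std, stride = c(60, 40, 40)), 8)
})

test_that("mirrored cubes hold the Z-flipped window", {
  ph <- get_phantom(31)
  roi <- box_to_roi3d(ph$boxes[[3]], ph$volume)
  std <- standardize_roi(roi)
  cubes <- sliding_windows(std, mirror = TRUE)
  d1 <- cube_data(cubes[[5]])
  d2 <- cube_data(cubes[[36 + 5]])
  expect_equal(d2, d1[64:1, , ])
})

test_that("cube counts reproduce 144 per bilateral brain and 2304 for 16", {
  ph <- get_phantom(31)
  cubes <- build_training_cubes(list(ph), "MB_CAL")
  expect_length(cubes, 144)
  expect_length(build_training_cubes(list(ph), "CX"), 72)
  expect_equal(count_training_cubes(16, "bilateral"), 2304)
  expect_equal(count_training_cubes(16, "midline"), 1152)
  expect_equal(count_training_cubes(1, "bilateral"), 144)
  # count function agrees with explicit construction
  expect_equal(count_training_cubes(1, "bilateral"), length(cubes))
  # missing structure errors
  ph_noboxes <- ph
  ph_noboxes$boxes <- Filter(function(b) b$roi_class != "AL", ph$boxes)
  expect_error(build_training_cubes(list(ph_noboxes), "AL"), "no box")
})

test_that("stitch equals the per-voxel accumulation oracle", {
  # constant probabilities through a full tiling stay constant
  tile <- sliding_windows(standardize_roi(array(0, c(64, 80, 80))),
                          stride = c(60, 40, 40))
  const <- lapply(tile, function(cb)
    list(offset = cb$offset, mirrored = FALSE,
         probs = array(rep(c(0.3, 0.7), each = prod(c(64, 128, 128))),
                       c(64, 128, 128, 2))))
  st <- stitch(const)
  expect_true(all(abs(st[, , , 1] - 0.3) < 1e-12))

  # random probabilities (with mirrored members) vs a per-voxel oracle
  withr::with_seed(42, {
    rand <- lapply(seq_along(tile), function(i) {
      p <- array(runif(prod(c(64, 128, 128))), c(64, 128, 128))
      list(offset = tile[[i]]$offset, mirrored = i %% 2 == 0,
           probs = array(c(p, 1 - p), c(64, 128, 128, 2)))
    })
    st2 <- stitch(rand)
    # probabilities sum to 1 everywhere
    expect_lt(max(abs(st2[, , , 1] + st2[, , , 2] - 1)), 1e-9)
    # oracle: direct accumulation at sampled voxels
    for (k in 1:200) {
      v <- c(sample(124, 1), sample(168, 1), sample(168, 1))
      s <- 0; n <- 0
      for (cp in rand) {
        o <- cp$offset
        if (all(v > o & v <= o + c(64, 128, 128))) {
          loc <- v - o
          p <- cp$probs
          if (cp$mirrored) loc[1] <- 64 + 1 - loc[1]
          s <- s + p[loc[1], loc[2], loc[3], 2]
          n <- n + 1
        }
      }
      expect_gte(n, 1)
      expect_equal(st2[v[1], v[2], v[3], 2], s / n, tolerance = 1e-6)
    }
  })
})

test_that("restore inverts standardization onto the original canvas", {
  # all-background probabilities restore to an empty labelling
  ph <- get_phantom(31)
  roi <- box_to_roi3d(ph$boxes[[3]], ph$volume)
  std <- standardize_roi(roi)
  empty <- array(rep(c(0.9, 0.1), each = prod(c(124, 168, 168))),
                 c(124, 168, 168, 2))
  lv <- restore(empty, std$geometry, dim(ph$volume$data))
  expect_equal(sum(lv$data), 0)
  # exact 0.5/0.5 ties resolve to background
  ties <- array(0.5, c(124, 168, 168, 2))
  expect_equal(sum(restore(ties, std$geometry, dim(ph$volume$data))$data), 0)
})

test_that("standardize -> restore round trip keeps 3D IoU >= 0.9", {
  ph <- get_phantom(31)
  for (bi in c(3, 4, 5)) {     # both MB_CAL sides and the CX box
    b <- ph$boxes[[bi]]
    roi <- box_to_roi3d(b, ph$volume)
    m <- ph$masks[[b$roi_class]]$data[, (roi$yrange[1] + 1):roi$yrange[2],
                                      (roi$xrange[1] + 1):roi$xrange[2]]
    std <- standardize_roi(roi, mask = m)
    back <- restore(std$mask, std$geometry, dim(ph$volume$data))
    # compare against this component only (inside the ROI footprint)
    ref <- array(0L, dim(ph$volume$data))
    ref[, (roi$yrange[1] + 1):roi$yrange[2], (roi$xrange[1] + 1):roi$xrange[2]] <- m
    expect_gte(iou3d(back$data, ref), 0.9)
  }
})
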