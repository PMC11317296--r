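# morphometry: component filter, bilateral volumes, hemispheres, cohorts

# rasterize a sphere into an existing array
add_sphere <- function(arr, center, r) {
  d <- dim(arr)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3])
    if (sum((c(z, y, x) - center)^2) <= r^2) arr[z, y, x] <- 1L
  arr
}

two_sphere_mask <- function(r_left = 4, r_right = 4, shape = c(16, 24, 40)) {
  arr <- array(0L, shape)
  arr <- add_sphere(arr, c(8, 12, 10), r_left)
  add_sphere(arr, c(8, 12, 30), r_right)
}

test_that("component filter accepts exactly-two balanced objects", {
  fd <- component_filter(two_sphere_mask(4, 4))
  expect_true(fd$passed)
  expect_equal(fd$n_components, 2)
  expect_equal(fd$volumes[1], fd$volumes[2])
})

test_that("component filter rejects imbalance, wrong counts and empties", {
  # volume ratio > 2: radii 5 vs 3 give ~515 vs ~123 voxels
  fd <- component_filter(two_sphere_mask(5, 3))
  expect_equal(fd$n_components, 2)
  expect_gt(fd$volumes[1], 2 * fd$volumes[2])
  expect_false(fd$passed)
  # explicit numeric rule: volumes 1000 vs 400 would fail since 1000 > 800
  expect_false(1000 <= 2 * 400)

  three <- add_sphere(two_sphere_mask(3, 3, c(16, 40, 40)), c(8, 30, 20), 3)
  fd3 <- component_filter(three)
  expect_equal(fd3$n_components, 3)
  expect_false(fd3$passed)

  fd0 <- component_filter(array(0L, c(4, 4, 4)))
  expect_false(fd0$passed)
  expect_equal(fd0$n_components, 0)
})

test_that("26-connectivity joins diagonal voxels, 6-connectivity does not", {
  arr <- array(0L, c(3, 3, 3))
  arr[1, 1, 1] <- 1L; arr[2, 2, 2] <- 1L
  expect_equal(component_filter(arr, connectivity = 26)$n_components, 1)
  expect_equal(component_filter(arr, connectivity = 6)$n_components, 2)
})

test_that("component filter is invariant to axis flips (voxel permutation)", {
  m <- two_sphere_mask(4, 3)
  flipped <- m[rev(seq_len(dim(m)[1])), , rev(seq_len(dim(m)[3]))]
  a <- component_filter(m); b <- component_filter(flipped)
  expect_equal(a$volumes, b$volumes)
  expect_equal(a$passed, b$passed)
})

test_that("bilateral volumes carry the documented sign convention", {
  m <- two_sphere_mask(4, 4)
  bv <- bilateral_volumes(m, midline_x = 20)
  expect_equal(bv$percent_diff, 0)
  expect_equal(bv$v_left, bv$v_right)

  m2 <- two_sphere_mask(3, 4)           # right larger
  bv2 <- bilateral_volumes(m2, midline_x = 20)
  expect_gt(bv2$percent_diff, 0)
  m3 <- two_sphere_mask(4, 3)           # left larger -> negative
  bv3 <- bilateral_volumes(m3, midline_x = 20)
  expect_lt(bv3$percent_diff, 0)
  expect_equal(bv2$percent_diff, -bv3$percent_diff)   # antisymmetry
  # the formula itself: v_l = 90, v_r = 110 -> +20
  expect_equal(100 * (110 - 90) / ((110 + 90) / 2), 20)

  # both centroids on one side: fall back with a warning
  expect_warning(bvs <- bilateral_volumes(m2, midline_x = 39), "same side")
  expect_true(bvs$side_flag)
  # physical units
  bvu <- bilateral_volumes(m, 20, voxel_size = c(0.32, 0.32, 1))
  expect_equal(bvu$v_left_um3, bv$v_left * 0.32 * 0.32 * 1)
})

test_that("hemisphere difference matches the voxel-count oracle", {
  m <- two_sphere_mask(4, 4)
  expect_equal(hemisphere_difference(m, 20), 0)
  expect_error(hemisphere_difference(m, 0), "empty hemisphere")

  ph <- generate_phantom(tiny_phantom_spec(seed = 51, asymmetry = 0.05,
                                           asymmetric_classes = "all"),
                         keep_volume = FALSE)
  tissue <- pmax(ph$masks$AL$data, ph$masks$MB_CAL$data)  # bilateral classes
  got <- hemisphere_difference(tissue, ph$midline_x)
  idx <- which(tissue > 0)
  xs <- (idx - 1) %/% (dim(tissue)[1] * dim(tissue)[2])
  vl <- sum(xs < ph$midline_x); vr <- sum(xs >= ph$midline_x)
  expect_equal(got, 100 * (vr - vl) / ((vl + vr) / 2))
  expect_lt(abs(got - 5), 3.5)    # planted 5% up to tiny-raster discretization
})

test_that("cohort summaries count exceedances and extrapolate validity", {
  expect_equal(cohort_summary(rep(0, 12))$fraction_exceed, 0)
  s <- cohort_summary(c(0, 3, -12, 25, 9.9, -10.01), threshold_pct = 10)
  expect_equal(s$n_exceed, 3)
  expect_equal(s$fraction_exceed, 0.5)
  # threshold 0 counts every nonzero difference
  expect_equal(cohort_summary(c(0, 1, -2, 0), threshold_pct = 0)$n_exceed, 2)
  expect_error(cohort_summary(numeric(0)), "empty")
})

test_that("cross-model consistency matches the closed-form OLS oracle", {
  a <- c(-12, -3, 0, 4, 11, 20)
  r <- cross_model_consistency(a, a)
  expect_equal(r$slope, 1); expect_equal(r$correlation, 1)
  expect_equal(cross_model_consistency(a, 2 * a)$slope, 2)
  withr::with_seed(34, {
    b <- 0.9 * a + rnorm(6, 0, 1)
    fit <- cross_model_consistency(a, b)
    # normal equations by hand
    slope <- sum((a - mean(a)) * (b - mean(b))) / sum((a - mean(a))^2)
    expect_equal(fit$slope, slope)
    expect_equal(fit$intercept, mean(b) - slope * mean(a))
  })
  expect_error(cross_model_consistency(a, a[-1]), "equal length")
  expect_error(cross_model_consistency(c(1, 1, 1), c(1, 2, 3)), "variance")
})
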