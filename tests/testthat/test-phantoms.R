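# synthetic_phantoms: geometry, planted asymmetry, determinism

test_that("generation is deterministic for a fixed seed", {
  a <- generate_phantom(tiny_phantom_spec(seed = 11))
  b <- generate_phantom(tiny_phantom_spec(seed = 11))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$masks$MB_CAL$data, b$masks$MB_CAL$data)
  c <- generate_phantom(tiny_phantom_spec(seed = 12))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("planted asymmetry is recovered by the voxel-count oracle", {
  ph0 <- get_phantom(21, asymmetry = 0)
  expect_lte(abs(neuropilseg:::phantom_percent_diff(ph0)), 2)
  ph20 <- get_phantom(22, asymmetry = 0.20)
  pd <- neuropilseg:::phantom_percent_diff(ph20)
  expect_gte(pd, 18); expect_lte(pd, 22)
  # non-asymmetric classes stay symmetric
  expect_lte(abs(neuropilseg:::phantom_percent_diff(ph20, "AL")), 2)
})

test_that("asymmetry is recovered across seeds and magnitudes (property)", {
  for (i in 1:4) {
    a <- c(-0.15, 0, 0.1, 0.25)[i]
    ph <- generate_phantom(tiny_phantom_spec(seed = 40 + i, asymmetry = a),
                           keep_volume = FALSE)
    # tiny rasters discretize more coarsely; allow 3.5 points
    expect_lte(abs(neuropilseg:::phantom_percent_diff(ph) - 100 * a), 3.5)
  }
})

test_that("emitted boxes fully contain the mask projections", {
  ph <- get_tiny_phantom(2)
  for (b in ph$boxes)
    expect_true(coverage_success(b, component_projection(ph, b)))
})

test_that("bilateral structures have two components separated by the midline", {
  ph <- get_tiny_phantom(3)
  for (cls in c("AL", "MB_CAL")) {
    lab <- neuropilseg:::label_components(ph$masks[[cls]]$data)
    expect_equal(lab$n_components, 2)
    d <- dim(ph$masks[[cls]]$data)
    xs <- (lab$idx - 1) %/% (d[1] * d[2])
    cx <- tapply(xs, lab$membership, mean)
    expect_equal(sum(cx < ph$midline_x), 1)
  }
  lab <- neuropilseg:::label_components(ph$masks$CX$data)
  expect_equal(lab$n_components, 1)
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(asymmetry = 1.2), "asymmetry")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  # radii that cannot fit the volume
  st <- default_phantom_structures()
  st$CX$base_radii <- c(200, 200, 200)
  expect_error(generate_phantom(phantom_spec(structures = st)), "exceed")
})

test_that("cohorts are reproducible and honour the asymmetry sampler", {
  one <- generate_cohort(1, list(type = "fixed", values = 0), seed = 9,
                         base_spec = tiny_phantom_spec())
  expect_length(one, 1)

  coh_a <- generate_cohort(6, list(type = "normal", mean = 0, sd = 0.08),
                           seed = 5, base_spec = tiny_phantom_spec())
  coh_b <- generate_cohort(6, list(type = "normal", mean = 0, sd = 0.08),
                           seed = 5, base_spec = tiny_phantom_spec())
  expect_identical(lapply(coh_a, `[[`, "truth"), lapply(coh_b, `[[`, "truth"))

  # all-symmetric cohort: no exceedances at the 10% threshold
  coh0 <- generate_cohort(10, list(type = "fixed", values = 0), seed = 6,
                          base_spec = tiny_phantom_spec())
  pd0 <- vapply(coh0, neuropilseg:::phantom_percent_diff, numeric(1))
  expect_equal(sum(abs(pd0) > 10), 0)

  # half at 0, half at 15%: exceedance fraction 0.5 by the mask oracle
  coh <- generate_cohort(50, list(type = "fixed", values = c(0, 0.15)),
                         seed = 7, base_spec = tiny_phantom_spec())
  pd <- vapply(coh, neuropilseg:::phantom_percent_diff, numeric(1))
  expect_equal(mean(abs(pd) > 10), 0.5)
})

test_that("light cohorts drop the intensity volume but keep the truth", {
  coh <- generate_cohort(2, list(type = "fixed", values = 0.1), seed = 8,
                         base_spec = tiny_phantom_spec(), keep_volume = FALSE)
  expect_null(coh[[1]]$volume)
  expect_s3_class(coh[[1]]$masks$MB_CAL, "label_volume")
  expect_error(generate_cohort(3, list(type = "bogus"), seed = 1), "sampler")
})
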