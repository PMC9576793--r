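small_cfg <- function(seed, ...) {
  phantom_config(shape = c(24, 36, 36), n_anchor = 2, n_midlevel = 2,
                 n_small_hard = 2, radius_anchor_mm = c(5, 8),
                 radius_midlevel_mm = c(3.5, 5),
                 radius_small_hard_mm = c(2, 3), seed = seed, ...)
}

test_that("phantom generation is a pure function of (config, seed)", {
  a <- generate_phantom(small_cfg(7))
  b <- generate_phantom(small_cfg(7))
  expect_identical(a$image$data, b$image$data)
  expect_identical(lapply(a$labels$masks, `[[`, "data"),
                   lapply(b$labels$masks, `[[`, "data"))
  c <- generate_phantom(small_cfg(8))
  expect_false(identical(a$image$data, c$image$data))
})

test_that("a 2/2/2 phantom yields six nonempty, disjoint, in-bounds masks", {
  ph <- generate_phantom(small_cfg(7))
  expect_length(ph$labels$masks, 6L)
  reg <- build_registry()
  occ <- array(0L, dim(ph$image$data))
  for (nm in names(ph$labels$masks)) {
    expect_true(nm %in% reg$name)
    m <- ph$labels$masks[[nm]]$data
    expect_gt(sum(m), 0)
    # strictly inside the bounds: no voxel on any face
    expect_equal(sum(m[c(1, dim(m)[1]), , ]), 0)
    expect_equal(sum(m[, c(1, dim(m)[2]), ]), 0)
    expect_equal(sum(m[, , c(1, dim(m)[3])]), 0)
    occ <- occ + m
  }
  expect_lte(max(occ), 1L)  # rejection sampling forbids overlap
})

test_that("realized contrast matches the configured offset (Monte Carlo)", {
  # anchor contrast 300, S&H contrast 30, noise sd 10: the mean
  # intensity inside a mask minus the background mean estimates the
  # stratum's contrast parameter
  est <- vapply(1:20, function(s) {
    ph <- generate_phantom(phantom_config(
      shape = c(20, 28, 28), n_anchor = 1, n_midlevel = 0,
      n_small_hard = 1, radius_anchor_mm = c(5, 7),
      radius_small_hard_mm = c(2, 3), contrast_anchor = 300,
      contrast_small_hard = 30, noise_sd = 10, seed = s))
    a <- ph$labels$masks[[1]]$data == 1
    s_ <- ph$labels$masks[[2]]$data == 1
    bg <- !(a | s_)
    c(mean(ph$image$data[a]) - mean(ph$image$data[bg]),
      mean(ph$image$data[s_]) - mean(ph$image$data[bg]))
  }, c(0, 0))
  sem <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_lt(abs(mean(est[1, ]) - 300), 3 * sem[1] + 1e-9)
  expect_lt(abs(mean(est[2, ]) - 30), 3 * sem[2] + 1e-9)
  # stratum contrast ordering in expectation
  expect_gt(mean(est[1, ]), mean(est[2, ]))
})

test_that("the analytic dose field follows its Gaussian closed form", {
  m <- sphere_mask(c(21, 21, 45), c(1, 1, 1), c(10, 10, 10), 5)
  cfg <- dose_field_config(prescription_dose = 70, falloff_sigma_mm = 20,
                           background_dose = 0)
  d <- generate_dose_grid(m, cfg)
  expect_equal(d$data[11, 11, 11], 70)  # centroid voxel
  expect_gte(min(d$data), 0)
  # at exactly sigma = 20 mm from the centroid: exp(-1/2)
  expect_equal(d$data[11, 11, 31], 70 * exp(-0.5), tolerance = 1e-12)
  # background floor
  m2 <- sphere_mask(c(21, 21, 21), c(1, 1, 1), c(10, 10, 10), 5)
  cfg2 <- dose_field_config(70, 10, background_dose = 5)
  d2 <- generate_dose_grid(m2, cfg2)
  expect_gte(min(d2$data), 5)
  expect_error(generate_dose_grid(mask3d(array(0L, c(4, 4, 4))), cfg),
               "empty")
})

test_that("dose grids can be coarser than the mask grid", {
  m <- sphere_mask(c(20, 20, 20), c(1.5, 1.5, 1.5), c(10, 10, 10), 6)
  d <- generate_dose_grid(m, dose_field_config(), dose_spacing = 3)
  expect_equal(d$spacing, c(3, 3, 3))
  expect_equal(dim(d$data), c(10L, 10L, 10L))
})

test_that("mask perturbation: identity at 0, deterministic, monotone", {
  m <- sphere_mask(c(30, 44, 44), c(1.5, 1.5, 1.5), c(15, 22, 22), 20)
  expect_identical(perturb_mask(m, 0, seed = 1)$data, m$data)
  p1 <- perturb_mask(m, 2, seed = 1)
  p2 <- perturb_mask(m, 2, seed = 1)
  expect_identical(p1$data, p2$data)
  expect_false(identical(p1$data, perturb_mask(m, 2, seed = 2)$data))
  # mean DSC against the original decreases with magnitude
  d1 <- mean(vapply(1:12, function(s)
    dsc(m, perturb_mask(m, 1, seed = s)), 0))
  d3 <- mean(vapply(1:12, function(s)
    dsc(m, perturb_mask(m, 3, seed = s)), 0))
  expect_lt(d3, d1)
  expect_lt(d1, 1)
})
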