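uniform_dose <- function(val, dim3 = c(6, 6, 6), sp = c(1, 1, 1))
  dose_grid(array(val, dim3), sp)

test_that("mean/max dose match direct summation on shared grids", {
  set.seed(20)
  m <- mask3d(random_mask_array(c(6, 6, 6)), c(1, 1, 1))
  expect_equal(mean_dose(m, uniform_dose(50)), 50)
  expect_equal(max_dose(m, uniform_dose(50)), 50)
  two <- array(0L, c(6, 6, 6)); two[1, 1, 1] <- 1L; two[2, 1, 1] <- 1L
  dg <- uniform_dose(0); dg$data[1, 1, 1] <- 40; dg$data[2, 1, 1] <- 60
  expect_equal(mean_dose(mask3d(two), dg), 50)
  expect_equal(max_dose(mask3d(two), dg), 60)
  for (i in 1:10) {
    mm <- mask3d(random_mask_array(c(6, 6, 6)))
    dd <- dose_grid(array(runif(216, 0, 70), c(6, 6, 6)))
    expect_equal(mean_dose(mm, dd), mean(dd$data[mm$data == 1]))
    expect_equal(max_dose(mm, dd), max(dd$data[mm$data == 1]))
  }
  expect_error(mean_dose(mask3d(array(0L, c(6, 6, 6))), uniform_dose(1),
                         name = "brainstem"), "brainstem")
})

test_that("masks resample to a coarser dose grid by nearest neighbour", {
  # mask on 1 mm grid, dose on 2 mm grid: dose voxel centers at 0, 2, 4
  # mm map to mask voxels 0, 2, 4
  m <- array(0L, c(8, 8, 8)); m[1:4, 1:4, 1:4] <- 1L
  mk <- mask3d(m, c(1, 1, 1))
  dg <- dose_grid(array(rep(c(10, 20, 30, 40), each = 1), c(4, 4, 4)),
                  c(2, 2, 2))
  sel <- stratseg:::resample_mask_to_dose(mk, dg)
  expect_equal(dim(sel), c(4L, 4L, 4L))
  expect_true(all(sel[1:2, 1:2, 1:2]))
  expect_false(any(sel[3:4, , ]))
})

test_that("DVH starts at 1, is non-increasing, and steps at uniform dose", {
  m <- mask3d(random_mask_array(c(6, 6, 6)))
  cv <- dvh(m, uniform_dose(10), bin_width_gy = 1)
  expect_equal(cv$frac_volume[1], 1)
  expect_true(all(diff(cv$frac_volume) <= 1e-12))
  expect_true(all(cv$frac_volume[cv$dose_gy <= 10] == 1))
  expect_true(all(cv$frac_volume[cv$dose_gy > 10] == 0))
  dd <- dose_grid(array(runif(216, 0, 70), c(6, 6, 6)))
  cv2 <- dvh(m, dd, 2)
  expect_equal(cv2$frac_volume[1], 1)
  expect_true(all(diff(cv2$frac_volume) <= 1e-12))
  expect_equal(tail(cv2$frac_volume, 1), 0)
  expect_error(dvh(m, dd, 0), "positive")
})

test_that("direct dose differences follow their defining ratio", {
  # hand-built: ref mean 50 Gy, substitute mean 55 Gy -> +10%
  dg <- uniform_dose(0, c(8, 8, 8))
  dg$data[1, 1, 1] <- 40; dg$data[2, 1, 1] <- 60  # ref: mean 50, max 60
  dg$data[3, 1, 1] <- 50                          # sub: mean 55, max 60
  ref_m <- array(0L, c(8, 8, 8)); ref_m[1:2, 1, 1] <- 1L
  sub_m <- array(0L, c(8, 8, 8)); sub_m[2:3, 1, 1] <- 1L
  ref <- structure_set(list(brainstem = mask3d(ref_m)), canonicalize = FALSE)
  sub <- structure_set(list(brainstem = mask3d(sub_m)), canonicalize = FALSE)
  rep <- diff_direct(ref, sub, dg)
  expect_equal(rep$mode, "direct")
  expect_equal(rep$per_oar$diff_mean_pct, 10)
  expect_equal(rep$per_oar$diff_max_pct, 0)
  # identity
  rep0 <- diff_direct(ref, ref, dg)
  expect_equal(rep0$per_oar$diff_mean_pct, 0)
  expect_equal(rep0$per_oar$diff_max_pct, 0)
  # zero reference dose is an explicit error naming the OAR
  zd <- uniform_dose(0, c(8, 8, 8))
  expect_error(diff_direct(ref, sub, zd), "brainstem")
})

test_that("clinical dose differences use the substitute dose grid", {
  # 8^3 grid, 2-voxel masks, hand-computed ratio
  dsub <- uniform_dose(0, c(8, 8, 8))
  dsub$data[1, 1, 1] <- 30; dsub$data[2, 1, 1] <- 50  # ref on sub grid
  dsub$data[5, 5, 5] <- 48; dsub$data[6, 5, 5] <- 32  # sub on sub grid
  ref_m <- array(0L, c(8, 8, 8)); ref_m[1:2, 1, 1] <- 1L
  sub_m <- array(0L, c(8, 8, 8)); sub_m[5:6, 5, 5] <- 1L
  ref <- structure_set(list(pituitary = mask3d(ref_m)), canonicalize = FALSE)
  sub <- structure_set(list(pituitary = mask3d(sub_m)), canonicalize = FALSE)
  rep <- diff_clinical(ref, sub, dsub, substitute_name = "reader")
  expect_equal(rep$mode, "clinical")
  expect_equal(rep$substitute_name, "reader")
  # mean: (40 - 40) / 40 = 0% ; max: (48 - 50) / 50 = -4%
  expect_equal(rep$per_oar$diff_mean_pct, 0)
  expect_equal(rep$per_oar$diff_max_pct, -4)
  # identical contours: 0% regardless of the grid
  rep0 <- diff_clinical(ref, ref, dsub)
  expect_equal(rep0$per_oar$diff_mean_pct, 0)
  expect_equal(rep0$per_oar$diff_max_pct, 0)
})

test_that("percentage differences are invariant to global dose scaling", {
  set.seed(21)
  mk <- function() mask3d(random_mask_array(c(6, 6, 6)))
  ref <- structure_set(list(brainstem = mk(), pituitary = mk()),
                       canonicalize = FALSE)
  sub <- structure_set(list(brainstem = mk(), pituitary = mk()),
                       canonicalize = FALSE)
  dd <- dose_grid(array(runif(216, 1, 70), c(6, 6, 6)))
  r1 <- diff_direct(ref, sub, dd)
  dd3 <- dose_grid(3.7 * dd$data, dd$spacing, dd$origin)
  r2 <- diff_direct(ref, sub, dd3)
  expect_equal(r1$per_oar$diff_mean_pct, r2$per_oar$diff_mean_pct)
  expect_equal(r1$per_oar$diff_max_pct, r2$per_oar$diff_max_pct)
})
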