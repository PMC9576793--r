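test_that("DSC matches its definition on simple and degenerate cases", {
  sp <- c(1, 1, 1)
  a <- array(0L, c(4, 4, 4)); a[1:2, 1, 1] <- 1L; a[1:2, 2, 1] <- 1L
  b <- array(0L, c(4, 4, 4)); b[1:2, 1, 1] <- 1L; b[1:2, 3, 1] <- 1L
  # |A| = |B| = 4, |A n B| = 2 -> 0.5
  expect_equal(dsc(mask3d(a, sp), mask3d(b, sp)), 0.5)
  m <- mask3d(random_mask_array(c(5, 5, 5)), sp)
  expect_equal(dsc(m, m), 1)
  dis <- array(0L, c(5, 5, 5)); dis[5, 5, 5] <- 1L
  expect_equal(dsc(m, mask3d(dis * (1L - m$data), sp)), 0)
  e <- mask3d(array(0L, c(5, 5, 5)), sp)
  both <- dsc(e, e)
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "both_empty"))
  expect_error(dsc(m, mask3d(array(0L, c(4, 4, 4)))), "grids")
})

test_that("two single voxels 3 mm apart give HD = ASD = 3 mm", {
  a <- array(0L, c(5, 5, 5)); a[2, 2, 2] <- 1L
  b <- array(0L, c(5, 5, 5)); b[2, 2, 5] <- 1L
  ma <- mask3d(a, c(1, 1, 1)); mb <- mask3d(b, c(1, 1, 1))
  h <- hausdorff(ma, mb)
  expect_equal(h$hd_mm, 3)
  expect_equal(h$hd95_mm, 3)
  expect_equal(asd(ma, mb), 3)
  # same voxel offset under anisotropic spacing scales to 3 mm too
  a2 <- array(0L, c(5, 5, 5)); a2[2, 2, 2] <- 1L
  b2 <- array(0L, c(5, 5, 5)); b2[3, 2, 2] <- 1L
  expect_equal(asd(mask3d(a2, c(3, 1, 1)), mask3d(b2, c(3, 1, 1))), 3)
})

test_that("distance metrics equal the exhaustive oracle on random pairs", {
  set.seed(10)
  for (i in 1:25) {
    d3 <- sample(4:12, 3, replace = TRUE)
    sp <- sample(c(0.8, 1, 1.5, 2, 3), 3, replace = TRUE)
    a <- random_mask_array(d3)
    b <- random_mask_array(d3)
    ma <- mask3d(a, sp); mb <- mask3d(b, sp)
    orc <- oracle_surface_metrics(a, b, sp)
    h <- hausdorff(ma, mb)
    expect_lt(abs(h$hd_mm - orc$hd), 1e-9)
    expect_lt(abs(h$hd95_mm - orc$hd95), 1e-9)
    expect_lt(abs(asd(ma, mb) - orc$asd), 1e-9)
    expect_lte(h$hd95_mm, h$hd_mm + 1e-12)
  }
})

test_that("metrics are symmetric and distances scale with spacing", {
  set.seed(11)
  a <- mask3d(random_mask_array(c(8, 8, 8)), c(1, 2, 1))
  b <- mask3d(random_mask_array(c(8, 8, 8)), c(1, 2, 1))
  expect_equal(dsc(a, b), dsc(b, a))
  expect_equal(hausdorff(a, b)$hd_mm, hausdorff(b, a)$hd_mm)
  expect_equal(asd(a, b), asd(b, a))
  a2 <- mask3d(a$data, 2 * c(1, 2, 1)); b2 <- mask3d(b$data, 2 * c(1, 2, 1))
  expect_equal(hausdorff(a2, b2)$hd_mm, 2 * hausdorff(a, b)$hd_mm)
  expect_equal(asd(a2, b2), 2 * asd(a, b))
  expect_error(hausdorff(a, mask3d(array(0L, c(8, 8, 8)), c(1, 2, 1))),
               "empty")
})

test_that("evaluate_case reports per-OAR rows, stratum means and skips", {
  set.seed(12)
  sp <- c(1.5, 1.5, 1.5)
  mk <- function() mask3d(random_mask_array(c(8, 10, 10)), sp)
  ref <- structure_set(list(brainstem = mk(), parotid_left = mk(),
                            pituitary = mk()), canonicalize = FALSE)
  pred <- structure_set(list(brainstem = ref$masks$brainstem,
                             parotid_left = mk(),
                             lens_left = mk()), canonicalize = FALSE)
  rep <- evaluate_case(pred, ref)
  expect_setequal(rep$per_oar$oar, c("brainstem", "parotid_left"))
  expect_setequal(rep$skipped, c("pituitary", "lens_left"))
  expect_equal(rep$per_oar$dsc[rep$per_oar$oar == "brainstem"], 1)
  expect_equal(rep$per_oar$hd_mm[rep$per_oar$oar == "brainstem"], 0)
  expect_true(all(c("anchor", "mid-level") %in% rep$stratum_means$stratum))
  # identical sets: perfect everywhere
  perfect <- evaluate_case(ref, ref)
  expect_true(all(perfect$per_oar$dsc == 1))
  expect_true(all(perfect$per_oar$asd_mm == 0))
  expect_error(evaluate_case(
    structure_set(list(lens_left = mk()), canonicalize = FALSE),
    structure_set(list(brainstem = mk()), canonicalize = FALSE)),
    "no OAR names")
})
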