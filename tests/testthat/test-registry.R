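test_that("the registry partitions 42 OARs into 9/19/14 strata", {
  reg <- build_registry()
  expect_s3_class(reg, "oar_registry")
  expect_equal(nrow(reg), 42L)
  expect_equal(sum(reg$stratum == "anchor"), 9L)
  expect_equal(sum(reg$stratum == "mid-level"), 19L)
  expect_equal(sum(reg$stratum == "small_hard"), 14L)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_equal(reg$name[1], "brainstem")
  expect_equal(stratum_of("pituitary"), "small_hard")
})

test_that("every lateral pair has both sides with identical stratum", {
  reg <- build_registry()
  lefts <- reg$name[reg$laterality == "left"]
  for (l in lefts) {
    r <- sub("_left$", "_right", l)
    expect_true(r %in% reg$name, label = paste(l, "has a right partner"))
    expect_equal(reg$stratum[reg$name == l], reg$stratum[reg$name == r])
  }
  expect_equal(sum(reg$laterality == "left"),
               sum(reg$laterality == "right"))
})

test_that("class indices are bijective per stratum with background 0", {
  reg <- build_registry()
  for (s in unique(reg$stratum)) {
    idx <- reg$class_index[reg$stratum == s]
    expect_equal(sort(idx), seq_along(idx))  # 1..C, 0 reserved
  }
})

test_that("clinical-table spellings canonicalize through the synonym table", {
  expect_equal(canonical_name("TMJ_Lt"), "tmj_left")
  expect_equal(canonical_name("SMG_Rt"), "submandibular_right")
  expect_equal(canonical_name("Glottic area"), "glottic_area")
  expect_equal(canonical_name("BrainStem"), "brainstem")
  expect_equal(canonical_name("OpticChiasm"), "optic_chiasm")
  expect_equal(stratum_of("TempLobe_Rt"), "mid-level")
  expect_equal(stratum_of("Cochlea_Lt"), "small_hard")
})

test_that("unknown OAR names raise a lookup error with near matches", {
  expect_error(stratum_of("femur"), "unknown OAR")
  expect_error(canonical_name("parotid_lft"), "did you mean")
})

test_that("the registry round-trips through JSON with extents", {
  reg <- build_registry()
  reg$extent_z_mm[3] <- 12.5
  f <- withr::local_tempfile(fileext = ".json")
  registry_to_json(reg, f)
  back <- registry_from_json(f)
  expect_equal(back$name, reg$name)
  expect_equal(back$stratum, reg$stratum)
  expect_equal(back$extent_z_mm, reg$extent_z_mm)
})

test_that("extents are estimated from training labels in mm", {
  m <- array(0L, c(10, 10, 10))
  m[3:6, 2:9, 5] <- 1L  # 4 x 8 x 1 voxels
  ph <- list(image = volume3d(array(0, c(10, 10, 10)), c(2, 1, 1)),
             labels = structure_set(list(
               brainstem = mask3d(m, c(2, 1, 1))), canonicalize = FALSE))
  ts <- training_set(list(ph))
  reg <- estimate_extents(ts)
  i <- which(reg$name == "brainstem")
  expect_equal(reg$extent_z_mm[i], 8)  # 4 voxels * 2 mm
  expect_equal(reg$extent_y_mm[i], 8)
  expect_equal(reg$extent_x_mm[i], 1)
  expect_true(is.na(reg$extent_z_mm[reg$name == "pituitary"]))
})
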