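count_params <- function(net) length(unlist(stratseg:::net_params(net)))

test_that("a built backbone maps (in, D, H, W) to (out, D, H, W)", {
  gen <- genotype(rep("3D3", 6), levels = 2, base = 4)
  net <- build_backbone(gen, 1, 5, seed = 40)
  x <- array(rnorm(16 * 24 * 24), c(16, 24, 24, 1))
  y <- stratseg:::net_forward(net, x)
  expect_identical(dim(y), c(16L, 24L, 24L, 5L))
  # odd spatial extents are padded internally and cropped back
  x2 <- array(rnorm(9 * 13 * 15), c(9, 13, 15, 1))
  y2 <- stratseg:::net_forward(net, x2)
  expect_identical(dim(y2), c(9L, 13L, 15L, 5L))
  # mixed operator families build and run
  gen2 <- genotype(c("2D3", "P3D5", "3D5", "2D5", "P3D3", "3D3"),
                   levels = 2, base = 2)
  net2 <- build_backbone(gen2, 2, 3, seed = 40)
  y3 <- stratseg:::net_forward(net2, array(rnorm(8 * 8 * 8 * 2),
                                           c(8, 8, 8, 2)))
  expect_identical(dim(y3), c(8L, 8L, 8L, 3L))
})

test_that("too-small volumes fail with the minimum admissible shape", {
  net <- build_backbone(genotype(rep("3D3", 6), 2, 2), 1, 2, seed = 1)
  expect_error(stratseg:::net_forward(net, array(0, c(2, 8, 8, 1))),
               "minimum admissible shape is 4x4x4")
  net3 <- build_backbone(genotype(rep("3D3", 10), 3, 2), 1, 2, seed = 1)
  expect_error(stratseg:::net_forward(net3, array(0, c(4, 16, 16, 1))),
               "8x8x8")
})

test_that("identical genotype and seed give identical initializations", {
  gen <- genotype(rep("P3D3", 6), 2, 4)
  a <- build_backbone(gen, 1, 3, seed = 99)
  b <- build_backbone(gen, 1, 3, seed = 99)
  expect_identical(stratseg:::net_params(a), stratseg:::net_params(b))
  c <- build_backbone(gen, 1, 3, seed = 100)
  expect_false(identical(stratseg:::net_params(a),
                         stratseg:::net_params(c)))
})

test_that("parameter count matches a layer-by-layer hand count", {
  base <- 8; C <- 4
  net <- build_backbone(genotype(rep("3D3", 6), 2, base), 1, C, seed = 2)
  # encoder: 1->8, 8->8; bottleneck: 8->16, 16->16;
  # decoder: (16 up + 8 skip)->8, 8->8; head: 1x1x1 8->C
  chans <- list(c(1, 8), c(8, 8), c(8, 16), c(16, 16), c(24, 8), c(8, 8))
  conv_block <- function(cin, cout) 27 * cin * cout + cout + 2 * cout
  expected <- sum(vapply(chans, function(cc)
    conv_block(cc[1], cc[2]), 0)) + (8 * C + C)
  expect_equal(count_params(net), expected)
  # P3D blocks double the conv stages: check one substitution
  netp <- build_backbone(genotype(c("P3D3", rep("3D3", 5)), 2, base),
                         1, C, seed = 2)
  p3d_block <- function(cin, cout)
    (9 * cin * cout + 3 * cout) + (3 * cout * cout + 3 * cout)
  expect_equal(count_params(netp),
               expected - conv_block(1, 8) + p3d_block(1, 8))
})

test_that("whole-volume prediction is deterministic and shape-faithful", {
  gen <- genotype(rep("2D3", 6), 2, 2)
  net <- build_backbone(gen, 1, 3, seed = 7)
  x <- array(rnorm(12 * 20 * 20), c(12, 20, 20, 1))
  p1 <- stratseg:::net_predict(net, x, tile = c(8, 8, 8))
  p2 <- stratseg:::net_predict(net, x, tile = c(8, 8, 8))
  expect_identical(p1, p2)
  expect_identical(dim(p1), c(12L, 20L, 20L, 3L))
})
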