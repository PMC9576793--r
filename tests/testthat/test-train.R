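tiny_phantom <- function(seed = 3)
  generate_phantom(phantom_config(
    shape = c(16, 24, 24), n_anchor = 1, n_midlevel = 1, n_small_hard = 1,
    radius_anchor_mm = c(4, 6), radius_midlevel_mm = c(3, 4),
    radius_small_hard_mm = c(2, 2.8), seed = seed))

tiny_train_cfg <- function(iters, ...)
  train_config(iterations = iters, patch = c(8L, 12L, 12L), ...)

test_that("segmentation loss gradient matches numeric differentiation", {
  set.seed(60)
  lg <- array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3))
  lab <- array(sample(0:2, 64, TRUE), c(4, 4, 4))
  out <- stratseg:::seg_loss_grad(lg, lab, 3)
  for (idx in list(c(1, 1, 1, 1), c(2, 3, 4, 2), c(4, 4, 1, 3))) {
    eps <- 1e-6
    lp <- lg; lp[idx[1], idx[2], idx[3], idx[4]] <- lp[idx[1], idx[2], idx[3], idx[4]] + eps
    lm <- lg; lm[idx[1], idx[2], idx[3], idx[4]] <- lm[idx[1], idx[2], idx[3], idx[4]] - eps
    num <- (stratseg:::seg_loss_grad(lp, lab, 3)$loss -
            stratseg:::seg_loss_grad(lm, lab, 3)$loss) / (2 * eps)
    expect_equal(out$dlogits[idx[1], idx[2], idx[3], idx[4]], num,
                 tolerance = 1e-5)
  }
  # all-background patch: only cross-entropy, no Dice gradient
  lab0 <- array(0L, c(4, 4, 4))
  out0 <- stratseg:::seg_loss_grad(lg, lab0, 3)
  expect_equal(out0$dice, 1)
})

test_that("role arities follow the registry stratification", {
  expect_equal(stratseg:::role_arity("anchor_seg"),
               list(in_ch = 1L, out_ch = 10L))
  expect_equal(stratseg:::role_arity("mid_seg"),
               list(in_ch = 10L, out_ch = 20L))
  expect_equal(stratseg:::role_arity("sh_detect"),
               list(in_ch = 10L, out_ch = 14L))
  expect_equal(stratseg:::role_arity("sh_seg"),
               list(in_ch = 1L, out_ch = 15L))
})

test_that("branch training descends, reproduces, and logs losses", {
  ph <- tiny_phantom()
  ts <- training_set(list(ph))
  gen <- tiny_genotype()
  cls <- intersect(oar_names(stratum = "anchor"), names(ph$labels$masks))
  m1 <- train_branch(ts, "anchor_seg", gen,
                     tiny_train_cfg(12, classes = cls), seed = 5)
  expect_s3_class(m1, "branch_model")
  expect_equal(nrow(m1$log), 12L)
  expect_lt(mean(tail(m1$log$loss, 3)), mean(head(m1$log$loss, 3)))
  m2 <- train_branch(ts, "anchor_seg", gen,
                     tiny_train_cfg(12, classes = cls), seed = 5)
  expect_identical(stratseg:::net_params(m1$net),
                   stratseg:::net_params(m2$net))
  m3 <- train_branch(ts, "anchor_seg", gen,
                     tiny_train_cfg(12, classes = cls), seed = 6)
  expect_false(identical(stratseg:::net_params(m1$net),
                         stratseg:::net_params(m3$net)))
})

test_that("classes absent from every case are reported by name", {
  ph <- tiny_phantom()
  ts <- training_set(list(ph))
  expect_error(
    train_branch(ts, "anchor_seg", tiny_genotype(), tiny_train_cfg(2),
                 seed = 1),
    "cerebellum")
})

test_that("heatmap-regression training fits Gaussian targets", {
  ph <- tiny_phantom()
  ts <- training_set(list(ph))
  cls <- intersect(oar_names(stratum = "small_hard"),
                   names(ph$labels$masks))
  m <- train_branch(ts, "sh_detect", tiny_genotype(),
                    tiny_train_cfg(12, classes = cls), seed = 2)
  expect_equal(m$net$out_ch, 14L)
  expect_equal(m$net$in_ch, 10L)
  expect_lt(mean(tail(m$log$loss, 3)), mean(head(m$log$loss, 3)))
})

test_that("models round-trip through save/load", {
  ph <- tiny_phantom()
  ts <- training_set(list(ph))
  cls <- intersect(oar_names(stratum = "anchor"), names(ph$labels$masks))
  m <- train_branch(ts, "anchor_seg", tiny_genotype(),
                    tiny_train_cfg(2, classes = cls), seed = 1)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(stratseg:::net_params(back$net),
                   stratseg:::net_params(m$net))
  expect_equal(back$role, "anchor_seg")
})
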