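#' Branch training
#'
#' The four pipeline roles and their input/output contracts:
#'
#' * `anchor_seg` — input: the (z-scored) volume, 1 channel; output:
#'   softmax over 1 + C_anchor classes (background is class 0).
#' * `mid_seg` — input: volume plus the C_anchor anchor foreground
#'   probability maps, 1 + C_anchor channels; output: 1 + C_mid
#'   classes.
#' * `sh_detect` — input: volume plus anchor guidance, 1 + C_anchor
#'   channels; output: one regressed heatmap per S&H OAR, trained
#'   against 3D Gaussian targets centered at the organ centroids.
#' * `sh_seg` — input: the cropped volume of interest only, 1 channel;
#'   output: 1 + C_sh classes (one shared model over all S&H classes).
#'
#' Segmentation roles optimize soft-Dice plus cross-entropy;
#' `sh_detect` optimizes mean-squared error.  Training samples random
#' patches (biased toward foreground), updated with Adam.  During
#' training the guidance channels are the one-hot ground-truth anchor
#' masks (teacher guidance); at inference they are the anchor branch's
#' predicted probabilities.
#'
#' @param iterations number of gradient steps.
#' @param patch patch size in voxels (z, y, x).
#' @param lr Adam learning rate.
#' @param batch patches per gradient step; with `batch >= 2` the first
#'   patch of every step is forced to be foreground-centered and the
#'   rest are sampled by the `fg_prob` coin, so each update sees both
#'   structure and background context.
#' @param fg_prob probability of centering a non-forced patch on a
#'   foreground voxel rather than sampling uniformly.
#' @param sigma_mm standard deviation (mm) of the Gaussian heatmap
#'   targets for `sh_detect`.
#' @param classes optional character vector restricting the trained
#'   class complement to a subset of the role's registry stratum (the
#'   network arity still follows the full registry).
#' @param jitter_vox uniform jitter (voxels) applied to
#'   structure-centered patch centers.
#' @param fg_weight cross-entropy weight of foreground voxels relative
#'   to background (foreground occupies a few percent of a patch).
#' @return `train_config()` returns a `"train_config"` list.
#' @export
train_config <- function(iterations = 200L, patch = c(32L, 32L, 32L),
                         lr = 5e-3, batch = 2L, fg_prob = 0.5,
                         sigma_mm = 3, classes = NULL, jitter_vox = 3L,
                         fg_weight = 3) {
  structure(list(iterations = as.integer(iterations),
                 patch = as.integer(patch), lr = lr,
                 batch = as.integer(batch), fg_prob = fg_prob,
                 sigma_mm = sigma_mm, classes = classes,
                 jitter_vox = as.integer(jitter_vox),
                 fg_weight = fg_weight),
            class = "train_config")
}

ROLES <- c("anchor_seg", "mid_seg", "sh_detect", "sh_seg")

role_stratum <- function(role) {
  switch(role, anchor_seg = "anchor", mid_seg = "mid-level",
         sh_detect = "small_hard", sh_seg = "small_hard",
         stop("unknown role '", role, "'"))
}

# input/output channel counts of a role under a registry
role_arity <- function(role, registry = build_registry()) {
  ca <- n_classes(registry, "anchor")
  cm <- n_classes(registry, "mid-level")
  cs <- n_classes(registry, "small_hard")
  switch(role,
         anchor_seg = list(in_ch = 1L, out_ch = ca + 1L),
         mid_seg = list(in_ch = 1L + ca, out_ch = cm + 1L),
         sh_detect = list(in_ch = 1L + ca, out_ch = cs),
         sh_seg = list(in_ch = 1L, out_ch = cs + 1L),
         stop("unknown role '", role, "'"))
}

znorm <- function(x) {
  s <- sd(as.vector(x))
  if (s == 0) s <- 1
  (x - mean(x)) / s
}

# ground-truth one-hot anchor guidance channels (foreground only)
anchor_onehot <- function(labels, registry) {
  nms <- oar_names(registry, "anchor")
  d <- labels$dim
  g <- array(0, c(d, length(nms)))
  for (i in seq_along(nms))
    if (nms[i] %in% names(labels$masks))
      g[, , , i] <- labels$masks[[nms[i]]]$data
  g
}

# class label map (0 = background) for one stratum
label_map <- function(labels, registry, stratum) {
  nms <- oar_names(registry, stratum)
  lab <- array(0L, labels$dim)
  for (i in seq_along(nms))
    if (nms[i] %in% names(labels$masks))
      lab[labels$masks[[nms[i]]]$data != 0] <- i
  lab
}

# assemble the network input x, target y, and foreground voxel index
# list for one case under one role
prepare_role_case <- function(case, role, registry = build_registry(),
                              sigma_mm = 3) {
  img <- znorm(case$image$data)
  d <- dim(img)
  labels <- case$labels
  stratum <- role_stratum(role)
  x <- if (role %in% c("mid_seg", "sh_detect")) {
    g <- anchor_onehot(labels, registry)
    array(c(img, g), c(d, 1L + dim(g)[4]))
  } else array(img, c(d, 1L))

  if (role == "sh_detect") {
    nms <- oar_names(registry, "small_hard")
    y <- array(0, c(d, length(nms)))
    for (i in seq_along(nms))
      if (nms[i] %in% names(labels$masks) &&
          mask_volume_vox(labels$masks[[nms[i]]]) > 0) {
        ctr <- round(mask_centroid(labels$masks[[nms[i]]]))
        y[, , , i] <- gaussian_target(ctr, sigma_mm, case$image)
      }
  } else {
    y <- label_map(labels, registry, stratum)
  }
  fg <- which(label_map(labels, registry, stratum) != 0L)
  # voxels of any structure regardless of stratum: hard negatives for
  # the roles that must reject other strata's structures
  all_fg <- integer(0)
  for (nm in names(labels$masks))
    all_fg <- c(all_fg, which(labels$masks[[nm]]$data != 0L))
  list(x = x, y = y, dim = d, fg = fg, all_fg = all_fg,
       spacing = case$image$spacing)
}

# sample a patch (0-based start); fg_prob of the time centered on a
# random foreground voxel
sample_patch <- function(sample, patch, fg_prob, center = NULL) {
  d <- sample$dim
  patch <- pmin(patch, d)
  if (is.null(center)) {
    if (length(sample$fg) > 0 && runif(1) < fg_prob) {
      v <- sample$fg[sample.int(length(sample$fg), 1L)] - 1L
      center <- c(v %% d[1], (v %/% d[1]) %% d[2], v %/% (d[1] * d[2]))
    }
  }
  start <- if (is.null(center)) {
    vapply(1:3, function(a)
      sample.int(d[a] - patch[a] + 1L, 1L) - 1L, 0L)
  } else {
    pmin(pmax(as.integer(round(center - patch / 2)), 0L), d - patch)
  }
  iz <- start[1] + seq_len(patch[1]); iy <- start[2] + seq_len(patch[2])
  ix <- start[3] + seq_len(patch[3])
  x <- sample$x[iz, iy, ix, , drop = FALSE]
  y <- if (length(dim(sample$y)) == 4L)
    sample$y[iz, iy, ix, , drop = FALSE]
  else sample$y[iz, iy, ix, drop = FALSE]
  list(x = x, y = y, start = start)
}

softmax_channels <- function(logits) {
  d <- dim(logits)
  n <- prod(d[1:3])
  lm <- matrix(logits, n, d[4])
  m <- lm[cbind(seq_len(n), max.col(lm, "first"))]
  e <- exp(lm - m)
  p <- e / rowSums(e)
  array(p, d)
}

# soft-Dice + foreground-weighted cross-entropy loss and its gradient
# wrt the logits.  Foreground voxels are rare (a few percent of a
# patch), so they carry `fg_weight` times the background weight in the
# cross-entropy term.
seg_loss_grad <- function(logits, labels, n_cls, smooth = 1e-5,
                          fg_weight = 5) {
  d <- dim(logits)
  n <- prod(d[1:3])
  p <- matrix(softmax_channels(logits), n, n_cls)
  lab <- as.integer(labels) + 1L  # 1-based class column
  w <- ifelse(lab > 1L, fg_weight, 1)
  W <- sum(w)
  ce <- -sum(w * log(p[cbind(seq_len(n), lab)] + 1e-12)) / W
  donehot <- p
  donehot[cbind(seq_len(n), lab)] <- donehot[cbind(seq_len(n), lab)] - 1
  dlog_ce <- (w / W) * donehot

  # soft Dice over the foreground classes present in this patch; absent
  # classes carry no Dice gradient (they would otherwise dominate and
  # suppress all foreground on small patches)
  present <- sort(unique(lab[lab > 1L])) - 1L
  cf <- length(present)
  dLdp <- matrix(0, n, n_cls)
  dice <- 1
  if (cf > 0) {
    dice_sum <- 0
    for (c in present) {
      yc <- as.numeric(lab == c + 1L)
      pc <- p[, c + 1L]
      A <- 2 * sum(pc * yc) + smooth
      B <- sum(pc) + sum(yc) + smooth
      dice_sum <- dice_sum + A / B
      dLdp[, c + 1L] <- -(2 * yc * B - A) / B^2 / cf
    }
    dice <- dice_sum / cf
  }
  dlog_dice <- p * (dLdp - rowSums(dLdp * p))
  list(loss = ce + (1 - dice),
       dlogits = array(dlog_ce + dlog_dice, d),
       ce = ce, dice = dice)
}

# target-weighted mean-squared error for heatmap regression: the
# Gaussian bump occupies a vanishing fraction of a patch, so voxels
# are weighted 1 + (pos_weight - 1) * target to keep the peak's
# gradient from drowning in the zero background
mse_loss_grad <- function(pred, target, pos_weight = 100) {
  r <- pred - target
  w <- 1 + (pos_weight - 1) * target
  W <- sum(w)
  list(loss = sum(w * r^2) / W, dlogits = 2 * w * r / W)
}

#' @rdname train_config
#' @param train_set a [training_set()]; every class the run trains on
#'   must appear in at least one case.
#' @param role one of `"anchor_seg"`, `"mid_seg"`, `"sh_detect"`,
#'   `"sh_seg"`.
#' @param geno a [genotype()] fixing the backbone architecture.
#' @param config a `train_config()`.
#' @param seed integer seed; identical inputs and seed reproduce the
#'   final parameters exactly.
#' @param registry OAR registry.
#' @return `train_branch()` returns a `"branch_model"`: the trained
#'   network with its role tag, class names, genotype, config, seed,
#'   and a per-iteration loss log.
#' @export
train_branch <- function(train_set, role, geno, config = train_config(),
                         seed = 1L, registry = build_registry()) {
  stopifnot(inherits(train_set, "training_set"),
            inherits(geno, "genotype"), inherits(config, "train_config"))
  role <- match.arg(role, ROLES)
  set.seed(as.integer(seed))
  stratum <- role_stratum(role)
  class_names <- config$classes
  if (is.null(class_names)) class_names <- oar_names(registry, stratum)
  present <- unique(unlist(lapply(train_set$cases,
                                  function(cs) names(cs$labels$masks))))
  missing <- setdiff(class_names, present)
  if (length(missing))
    stop("classes absent from every training case: ",
         paste(missing, collapse = ", "))

  arity <- role_arity(role, registry)
  net <- build_backbone(geno, arity$in_ch, arity$out_ch)
  if (role != "sh_detect") {
    # background-prior head bias: foreground is rare, so start the
    # softmax there instead of spending early iterations learning it
    net$head$b[1] <- 2
  }
  samples <- lapply(train_set$cases, prepare_role_case, role = role,
                    registry = registry, sigma_mm = config$sigma_mm)
  params <- net_params(net)
  st <- adam_init(params)
  losses <- numeric(config$iterations)
  # the zoom-in branch only ever sees VOIs, so every patch is centered
  # on a structure; the detection branch must stay translation-honest,
  # so its structure-centered patches get jitter up to half the patch
  # (the target may land anywhere, never systematically at the center)
  all_fg_centered <- role == "sh_seg"
  jit <- if (role == "sh_detect") pmax(config$patch %/% 2L - 1L,
                                       config$jitter_vox)
         else rep(config$jitter_vox, 3)
  pick_center <- function(s, pool) {
    v <- pool[sample.int(length(pool), 1L)] - 1L
    c(v %% s$dim[1], (v %/% s$dim[1]) %% s$dim[2],
      v %/% (s$dim[1] * s$dim[2])) +
      vapply(jit, function(j) sample(-j:j, 1L), 0L)
  }
  for (it in seq_len(config$iterations)) {
    s <- samples[[sample.int(length(samples), 1L)]]
    gacc <- NULL
    lsum <- 0
    for (j in seq_len(config$batch)) {
      center <- NULL
      if ((j == 1L || all_fg_centered) && length(s$fg) > 0) {
        center <- pick_center(s, s$fg)      # forced role-foreground
      } else if (length(s$all_fg) > 0 &&
                 (role == "sh_detect" || it %% 2L == 0L)) {
        # structure-centered hard negative; detection takes one every
        # step (its spurious responses sit on other structures),
        # segmentation alternates it with a uniform draw
        center <- pick_center(s, s$all_fg)
      }
      pb <- sample_patch(s, config$patch, config$fg_prob, center = center)
      f <- net_forward(net, pb$x, keep_cache = TRUE)
      lg <- if (role == "sh_detect") mse_loss_grad(f$y, pb$y)
            else seg_loss_grad(f$y, pb$y, net$out_ch,
                               fg_weight = config$fg_weight)
      g <- net_backward(net, f$cache, lg$dlogits)
      gstep <- list(blocks = g$blocks, head = g$head)
      gacc <- if (is.null(gacc)) gstep else ptree_map2(`+`, gacc, gstep)
      lsum <- lsum + lg$loss
    }
    if (config$batch > 1L)
      gacc <- ptree_map2(function(a, b) a / config$batch, gacc, gacc)
    # segmentation: cosine learning-rate decay stabilizes the late
    # iterations; heatmap regression keeps a flat rate — the bump
    # amplitude is still growing when a decayed rate would freeze it
    lr_t <- if (role == "sh_detect") config$lr
            else config$lr * 0.5 * (1 + cos(pi * (it - 1) /
                                            config$iterations))
    upd <- adam_step(params, gacc, st, lr_t)
    params <- upd$params; st <- upd$state
    net <- set_net_params(net, params)
    losses[it] <- lsum / config$batch
  }
  structure(list(role = role, net = net, genotype = geno,
                 classes = class_names, registry = registry,
                 config = config, seed = as.integer(seed),
                 log = data.frame(iter = seq_len(config$iterations),
                                  loss = losses)),
            class = "branch_model")
}

#' @export
print.branch_model <- function(x, ...) {
  cat(sprintf("<branch_model> role %s, %d->%d channels, %d classes, %s\n",
              x$role, x$net$in_ch, x$net$out_ch, length(x$classes),
              paste(x$genotype$blocks, collapse = " ")))
  invisible(x)
}

#' Save / load a trained branch model
#'
#' Models are stored with their genotype, parameters, configuration
#' and seed so inference runs are reproducible.
#'
#' @param model a `"branch_model"`.
#' @param path file path (RDS).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "branch_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "branch_model")) stop("not a branch_model file: ", path)
  m
}
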