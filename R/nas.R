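#' Differentiable architecture search over the operator space
#'
#' Each searchable block of the backbone carries six learnable logits,
#' one per candidate operator.  During search the block computes the
#' softmax-weighted mixture of all candidates ([gamma_weights()],
#' [mixed_block_forward()]); network weights and architecture logits
#' are optimized by first-order alternating gradient descent on two
#' disjoint case-level partitions of the training set.  The final
#' discrete architecture takes, per block, the operator with the top
#' weight.
#'
#' @param state a search network (from the internals of
#'   [search_architecture()]) or any list with elements `alphas` (a
#'   blocks x 6 logit matrix), `levels`, `base`.
#' @return [derive_genotype()] returns a [genotype()]: per block the
#'   operator with maximal logit (equivalently maximal softmax weight;
#'   the softmax is order-preserving), ties broken toward the lowest
#'   index in the fixed ordering `r paste(OP_CODES, collapse = ", ")`.
#' @export
derive_genotype <- function(state) {
  a <- state$alphas
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  codes <- OP_CODES[apply(a, 1, which.max)]  # which.max = first max
  genotype(codes, levels = state$levels, base = state$base)
}

#' @rdname derive_genotype
#' @param levels,base backbone structure searched over (see
#'   [genotype()]).
#' @param epochs number of alternating-descent epochs; 0 returns the
#'   argmax of the uniform initial logits (all blocks operator
#'   `"2D3"`).
#' @param patch training patch size in voxels (z, y, x).
#' @param lr_weights,lr_alphas Adam learning rates for network weights
#'   and architecture logits.
#' @param weight_fraction fraction of cases in the weight-update
#'   partition (remainder updates the logits); default 2/3.
#' @param fg_prob probability that a sampled patch is centered on a
#'   foreground voxel.
#' @export
search_config <- function(levels = 2L, base = 4L, epochs = 5L,
                          patch = c(16L, 24L, 24L), lr_weights = 1e-3,
                          lr_alphas = 3e-3, weight_fraction = 2 / 3,
                          fg_prob = 0.8) {
  structure(list(levels = as.integer(levels), base = as.integer(base),
                 epochs = as.integer(epochs), patch = as.integer(patch),
                 lr_weights = lr_weights, lr_alphas = lr_alphas,
                 weight_fraction = weight_fraction, fg_prob = fg_prob),
            class = "search_config")
}

#' @rdname derive_genotype
#' @param train_set a [training_set()]; split at case level into
#'   disjoint weight-update and architecture-update partitions.
#' @param role one of `"anchor_seg"`, `"mid_seg"`, `"sh_detect"`,
#'   `"sh_seg"` (see [train_branch()] for the role contracts).
#' @param config a [search_config()].
#' @param seed integer seed controlling initialization, the partition
#'   split, and patch sampling; identical inputs and seed give
#'   identical genotypes.
#' @param registry OAR registry defining the role's class complement.
#' @export
search_architecture <- function(train_set, role,
                                config = search_config(), seed = 1L,
                                registry = build_registry()) {
  stopifnot(inherits(train_set, "training_set"),
            inherits(config, "search_config"))
  set.seed(as.integer(seed))
  arity <- role_arity(role, registry)
  net <- build_search_net(config$levels, config$base, arity$in_ch,
                          arity$out_ch)
  log <- data.frame()
  if (config$epochs > 0) {
    n <- train_set$n
    nw <- max(1L, floor(n * config$weight_fraction))
    if (nw >= n)
      stop("architecture-update partition is empty: need at least ",
           "one case outside the weight partition (n = ", n, ")")
    perm <- sample.int(n)
    w_idx <- perm[seq_len(nw)]
    a_idx <- perm[(nw + 1):n]
    samples <- lapply(train_set$cases, prepare_role_case, role = role,
                      registry = registry)
    params <- net_params(net)
    st_w <- adam_init(params)
    alphas <- net$alphas
    st_a <- adam_init(alphas)
    for (ep in seq_len(config$epochs)) {
      for (ci in sample(w_idx)) {
        g <- search_grad_step(net, samples[[ci]], role, config)
        upd <- adam_step(params, g$wgrads, st_w, config$lr_weights)
        params <- upd$params; st_w <- upd$state
        net <- set_net_params(net, params)
        log <- rbind(log, data.frame(epoch = ep, phase = "weights",
                                     loss = g$loss))
      }
      for (ci in sample(a_idx)) {
        g <- search_grad_step(net, samples[[ci]], role, config)
        upd <- adam_step(alphas, g$dalpha, st_a, config$lr_alphas)
        alphas <- upd$params; st_a <- upd$state
        net$alphas <- alphas
        log <- rbind(log, data.frame(epoch = ep, phase = "alphas",
                                     loss = g$loss))
      }
    }
  }
  gen <- derive_genotype(net)
  attr(gen, "alphas") <- net$alphas
  attr(gen, "log") <- log
  gen
}

# one patch forward/backward on the mixed network
search_grad_step <- function(net, sample, role, config) {
  pb <- sample_patch(sample, config$patch, config$fg_prob)
  f <- net_forward(net, pb$x, keep_cache = TRUE)
  lg <- if (role == "sh_detect") mse_loss_grad(f$y, pb$y)
        else seg_loss_grad(f$y, pb$y, net$out_ch)
  g <- net_backward(net, f$cache, lg$dlogits)
  list(loss = lg$loss, wgrads = list(blocks = g$blocks, head = g$head),
       dalpha = g$dalpha)
}

#' Serialize a genotype to / from JSON
#'
#' @param geno a [genotype()].
#' @param path file path.
#' @export
genotype_to_json <- function(geno, path) {
  jsonlite::write_json(list(levels = geno$levels, base = geno$base,
                            blocks = geno$blocks),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname genotype_to_json
#' @export
genotype_from_json <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  genotype(g$blocks, levels = g$levels, base = g$base)
}
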