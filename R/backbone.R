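#' Architecture genotypes
#'
#' A genotype is the discrete architecture of a backbone: one operator
#' code per searchable block (see [OP_CODES]) plus the structural
#' hyperparameters (resolution levels and base channel count).  The
#' backbone is an encoder-decoder with skip connections in which every
#' convolution block position is searchable: two blocks per encoder
#' level, two in the bottleneck, and two per decoder level, i.e.
#' `2 * (2 * levels - 1)` blocks in total.
#'
#' @param blocks character vector of operator codes, one per searchable
#'   block, in encoder-to-decoder order.
#' @param levels number of resolution levels (>= 2); each extra level
#'   adds a 2x downsampling stage.
#' @param base channel count at the finest resolution; deeper levels
#'   double it.
#' @return an object of class `"genotype"`.
#' @examples
#' genotype(rep("3D3", 6), levels = 2, base = 8)
#' @export
genotype <- function(blocks, levels = 2L, base = 8L) {
  levels <- as.integer(levels)
  if (levels < 2) stop("the backbone needs at least 2 levels")
  nb <- n_search_blocks(levels)
  if (length(blocks) != nb)
    stop("a ", levels, "-level backbone has ", nb, " searchable blocks; got ",
         length(blocks))
  bad <- setdiff(blocks, OP_CODES)
  if (length(bad))
    stop("unknown operator codes: ", paste(unique(bad), collapse = ", "))
  structure(list(blocks = as.character(blocks), levels = levels,
                 base = as.integer(base)),
            class = "genotype")
}

#' @rdname genotype
#' @export
n_search_blocks <- function(levels) 2L * (2L * as.integer(levels) - 1L)

# (cin, cout) of every searchable block, encoder-to-decoder order
backbone_plan <- function(levels, base, in_ch) {
  ch <- function(l) base * 2^l  # l is 0-based level
  plan <- list()
  for (l in 0:(levels - 2)) {
    cin <- if (l == 0) in_ch else ch(l - 1)
    plan <- c(plan, list(c(cin, ch(l)), c(ch(l), ch(l))))
  }
  plan <- c(plan, list(c(ch(levels - 2), ch(levels - 1)),
                       c(ch(levels - 1), ch(levels - 1))))
  for (l in (levels - 2):0)
    plan <- c(plan, list(c(ch(l + 1) + ch(l), ch(l)), c(ch(l), ch(l))))
  plan
}

#' Build a fixed backbone from a genotype
#'
#' Instantiates the encoder-decoder with the genotype's operator in
#' every block and a linear 1x1x1 output head.  Parameter
#' initialization is He-normal; pass a seed for reproducible builds.
#'
#' @param geno a [genotype()].
#' @param in_channels,out_channels network input/output channel counts.
#' @param seed optional integer seed for the parameter initialization.
#' @return an object of class `"backbone_net"`.
#' @export
build_backbone <- function(geno, in_channels, out_channels, seed = NULL) {
  stopifnot(inherits(geno, "genotype"), in_channels >= 1, out_channels >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  plan <- backbone_plan(geno$levels, geno$base, in_channels)
  blocks <- vector("list", length(plan))
  for (i in seq_along(plan))
    blocks[[i]] <- make_op(geno$blocks[i], plan[[i]][1], plan[[i]][2])
  head_cin <- geno$base
  head <- list(W = array(rnorm(head_cin * out_channels, 0,
                               sqrt(2 / head_cin)),
                         c(1, 1, 1, head_cin, out_channels)),
               b = numeric(out_channels))
  structure(list(genotype = geno, levels = geno$levels, base = geno$base,
                 in_ch = as.integer(in_channels),
                 out_ch = as.integer(out_channels),
                 blocks = blocks, head = head),
            class = "backbone_net")
}

# search network: every block holds all six candidate operators plus a
# row of architecture logits (initialized to zero = uniform weights)
build_search_net <- function(levels, base, in_channels, out_channels,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  levels <- as.integer(levels)
  if (levels < 2) stop("the backbone needs at least 2 levels")
  plan <- backbone_plan(levels, base, in_channels)
  blocks <- vector("list", length(plan))
  for (i in seq_along(plan))
    blocks[[i]] <- lapply(OP_CODES, make_op,
                          cin = plan[[i]][1], cout = plan[[i]][2])
  head_cin <- base
  head <- list(W = array(rnorm(head_cin * out_channels, 0,
                               sqrt(2 / head_cin)),
                         c(1, 1, 1, head_cin, out_channels)),
               b = numeric(out_channels))
  structure(list(levels = levels, base = as.integer(base),
                 in_ch = as.integer(in_channels),
                 out_ch = as.integer(out_channels),
                 alphas = matrix(0, length(plan), length(OP_CODES)),
                 blocks = blocks, head = head),
            class = "search_net")
}

pad_to_multiple <- function(x, m) {
  d <- dim(x)
  pd <- as.integer(ceiling(d[1:3] / m) * m)
  if (all(pd == d[1:3])) return(list(x = x, orig = d[1:3]))
  y <- array(0, c(pd, d[4]))
  y[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x
  list(x = y, orig = d[1:3])
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

# forward pass shared by fixed and search networks; records a tape of
# operations when keep_cache = TRUE so the backward pass can mirror it
net_forward <- function(net, x, keep_cache = FALSE) {
  x <- as_feature4(x)
  if (dim(x)[4] != net$in_ch)
    stop("input has ", dim(x)[4], " channels, network expects ", net$in_ch)
  minsz <- 2^net$levels
  if (any(dim(x)[1:3] < minsz))
    stop("volume too small for ", net$levels - 1,
         " poolings; minimum admissible shape is ",
         paste(rep(minsz, 3), collapse = "x"))
  mixed <- inherits(net, "search_net")
  pm <- pad_to_multiple(x, 2^(net$levels - 1))
  h <- pm$x
  tape <- list()
  rec <- function(r) if (keep_cache) tape[[length(tape) + 1L]] <<- r

  run_block <- function(h, bi) {
    f <- if (mixed)
      mixed_fwd(net$blocks[[bi]], net$alphas[bi, ], h, keep_cache)
    else
      op_fwd(net$blocks[[bi]], h, keep_cache)
    rec(list(type = "block", bi = bi, cache = f$cache))
    f$y
  }

  L <- net$levels
  skips <- vector("list", L - 1)
  bi <- 1L
  for (l in seq_len(L - 1)) {  # encoder levels 0..L-2
    h <- run_block(h, bi); bi <- bi + 1L
    h <- run_block(h, bi); bi <- bi + 1L
    skips[[l]] <- h
    rec(list(type = "save_skip", l = l))
    in_dim <- dim(h)
    pf <- cpp_maxpool2_fwd(as.vector(h), in_dim)
    rec(list(type = "pool", idx = pf$idx, in_dim = in_dim))
    h <- array(pf$y, c(in_dim[1:3] %/% 2L, in_dim[4]))
  }
  h <- run_block(h, bi); bi <- bi + 1L   # bottleneck
  h <- run_block(h, bi); bi <- bi + 1L
  for (l in rev(seq_len(L - 1))) {       # decoder levels L-2..0
    in_dim <- dim(h)
    h <- array(cpp_upsample2_fwd(as.vector(h), in_dim),
               c(in_dim[1:3] * 2L, in_dim[4]))
    rec(list(type = "up", in_dim = in_dim))
    c_up <- dim(h)[4]
    h <- concat_ch(h, skips[[l]])
    rec(list(type = "concat", l = l, c_up = c_up,
             c_skip = dim(skips[[l]])[4]))
    h <- run_block(h, bi); bi <- bi + 1L
    h <- run_block(h, bi); bi <- bi + 1L
  }
  rec(list(type = "head_in", h = if (keep_cache) h else NULL))
  y <- conv_fwd(h, net$head$W, net$head$b)
  od <- pm$orig
  y <- y[seq_len(od[1]), seq_len(od[2]), seq_len(od[3]), , drop = FALSE]
  if (keep_cache)
    list(y = y, cache = list(tape = tape, padded = dim(pm$x)[1:3],
                             orig = od))
  else y
}

# backward pass: walks the tape in reverse; returns parameter gradients
# (blocks + head; for a search net also per-block architecture logits)
net_backward <- function(net, cache, dy) {
  mixed <- inherits(net, "search_net")
  pd <- cache$padded
  od <- cache$orig
  if (!all(pd == od)) {
    full <- array(0, c(pd, dim(dy)[4]))
    full[seq_len(od[1]), seq_len(od[2]), seq_len(od[3]), ] <- dy
    dy <- full
  }
  tape <- cache$tape
  grads <- list(blocks = vector("list", length(net$blocks)),
                head = NULL)
  if (mixed) grads$dalpha <- matrix(0, nrow(net$alphas), ncol(net$alphas))

  # head
  top <- tape[[length(tape)]]
  stopifnot(top$type == "head_in")
  hb <- cpp_conv3d_bwd(as.vector(top$h), dim(top$h),
                       as.vector(net$head$W), dim(net$head$W),
                       as.vector(dy))
  grads$head <- list(W = array(hb$dw, dim(net$head$W)), b = hb$db)
  dh <- array(hb$dx, dim(top$h))

  dskips <- vector("list", net$levels - 1)
  for (ti in rev(seq_len(length(tape) - 1L))) {
    r <- tape[[ti]]
    if (r$type == "block") {
      if (mixed) {
        bk <- mixed_bwd(net$blocks[[r$bi]], r$cache, dh)
        grads$blocks[[r$bi]] <- bk$op_grads
        grads$dalpha[r$bi, ] <- bk$dalpha
      } else {
        bk <- op_bwd(net$blocks[[r$bi]], r$cache, dh)
        grads$blocks[[r$bi]] <- bk$stages
      }
      dh <- bk$dx
    } else if (r$type == "concat") {
      d <- dim(dh)
      dskips[[r$l]] <- dh[, , , r$c_up + seq_len(r$c_skip), drop = FALSE]
      dh <- dh[, , , seq_len(r$c_up), drop = FALSE]
      # undo the upsample that directly precedes every concat
    } else if (r$type == "up") {
      dh <- array(cpp_upsample2_bwd(as.vector(dh), dim(dh)),
                  c(dim(dh)[1:3] %/% 2L, dim(dh)[4]))
    } else if (r$type == "pool") {
      dh <- array(cpp_maxpool2_bwd(as.vector(dh), r$idx, r$in_dim),
                  r$in_dim)
    } else if (r$type == "save_skip") {
      dh <- dh + dskips[[r$l]]
    }
  }
  grads
}

# parameter tree of a network, aligned with the gradient tree that
# net_backward returns (architecture logits are kept separate)
net_params <- function(net) {
  strip <- function(op) lapply(op$stages, function(s)
    list(W = s$W, b = s$b, g = s$g, beta = s$beta))
  blocks <- if (inherits(net, "search_net"))
    lapply(net$blocks, function(cands) lapply(cands, strip))
  else lapply(net$blocks, strip)
  list(blocks = blocks, head = net$head)
}

set_net_params <- function(net, params) {
  put <- function(op, stages) {
    for (i in seq_along(op$stages)) {
      op$stages[[i]]$W <- stages[[i]]$W
      op$stages[[i]]$b <- stages[[i]]$b
      op$stages[[i]]$g <- stages[[i]]$g
      op$stages[[i]]$beta <- stages[[i]]$beta
    }
    op
  }
  if (inherits(net, "search_net")) {
    for (b in seq_along(net$blocks))
      for (k in seq_along(net$blocks[[b]]))
        net$blocks[[b]][[k]] <- put(net$blocks[[b]][[k]],
                                    params$blocks[[b]][[k]])
  } else {
    for (b in seq_along(net$blocks))
      net$blocks[[b]] <- put(net$blocks[[b]], params$blocks[[b]])
  }
  net$head <- params$head
  net
}

# sliding-window whole-volume prediction: tiles of the training patch
# size swept with a stride (default half-tile overlap), probabilities
# averaged where tiles overlap.  Overlap keeps every structure fully
# visible in at least one tile (a structure cut at a tile border loses
# the shape cues the network was trained on) and bounds memory; the
# per-tile window also matches the feature statistics the
# instance-normalized network saw during patch training.
net_predict <- function(net, x, tile = c(32L, 32L, 32L), stride = NULL) {
  x <- as_feature4(x)
  d <- dim(x)[1:3]
  tile <- pmin(as.integer(tile), d)
  if (is.null(stride)) stride <- pmax(tile %/% 2L, 1L)
  stride <- pmax(pmin(as.integer(stride), tile), 1L)
  starts <- lapply(1:3, function(a) {
    s <- seq(0L, d[a] - tile[a], by = stride[a])
    unique(c(s, d[a] - tile[a]))
  })
  acc <- array(0, c(d, net$out_ch))
  cnt <- array(0, d)
  for (sz in starts[[1]]) for (sy in starts[[2]]) for (sx in starts[[3]]) {
    iz <- sz + seq_len(tile[1]); iy <- sy + seq_len(tile[2])
    ix <- sx + seq_len(tile[3])
    yb <- net_forward(net, x[iz, iy, ix, , drop = FALSE])
    acc[iz, iy, ix, ] <- acc[iz, iy, ix, , drop = FALSE] + yb
    cnt[iz, iy, ix] <- cnt[iz, iy, ix] + 1
  }
  acc / as.vector(cnt)
}
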