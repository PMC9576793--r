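#' The searchable convolution operator space
#'
#' Every searchable block of the backbone chooses among six composite
#' operators.  A composite operator is convolution -> instance
#' normalization -> leaky-rectifier activation, with the convolution
#' kernel determining the operator family: in-plane 2D kernels (through
#' -plane extent 1), full 3D kernels, or pseudo-3D (P3D) operators that
#' chain an in-plane composite with a through-plane composite.  Each
#' family comes in kernel size 3 or 5, giving the fixed operator
#' ordering `2D3, 2D5, 3D3, 3D5, P3D3, P3D5` used for tie-breaking and
#' serialization.
#'
#' Feature maps are numeric arrays with dim (nz, ny, nx, channels);
#' axis 1 is the through-plane axis.  All operators use zero "same"
#' padding, so spatial shape is preserved.
#'
#' @name operator-space
NULL

#' @rdname operator-space
#' @format `OP_CODES` is the fixed character vector of the six operator
#'   codes in tie-breaking order.
#' @export
OP_CODES <- c("2D3", "2D5", "3D3", "3D5", "P3D3", "P3D5")

# kernel dims (z, y, x) of each conv stage of an operator
op_kernels <- function(code) {
  switch(code,
         "2D3" = list(c(1L, 3L, 3L)),
         "2D5" = list(c(1L, 5L, 5L)),
         "3D3" = list(c(3L, 3L, 3L)),
         "3D5" = list(c(5L, 5L, 5L)),
         "P3D3" = list(c(1L, 3L, 3L), c(3L, 1L, 1L)),
         "P3D5" = list(c(1L, 5L, 5L), c(5L, 1L, 1L)),
         stop("unknown operator code '", code, "'"))
}

IN_EPS <- 1e-5
LRELU_SLOPE <- 0.01

#' @rdname operator-space
#' @param code one of `OP_CODES`.
#' @param cin,cout input/output channel counts.
#' @return `make_op()` returns a `"conv_op"`: the operator descriptor
#'   with freshly initialized parameters (He-normal kernels, unit
#'   normalization gain, zero bias/shift).
#' @export
make_op <- function(code, cin, cout) {
  kerns <- op_kernels(code)
  stages <- list()
  c_in <- cin
  for (i in seq_along(kerns)) {
    k <- kerns[[i]]
    c_out <- cout  # P3D keeps cout through both stages
    fan_in <- prod(k) * c_in
    stages[[i]] <- list(
      W = array(rnorm(prod(k) * c_in * c_out, 0, sqrt(2 / fan_in)),
                c(k, c_in, c_out)),
      b = numeric(c_out),
      g = rep(1, c_out),
      beta = numeric(c_out))
    c_in <- c_out
  }
  structure(list(code = code, cin = cin, cout = cout, stages = stages),
            class = "conv_op")
}

as_feature4 <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) stop("feature maps must be 3D or 4D arrays")
  x
}

conv_fwd <- function(x, W, b) {
  xd <- dim(x); wd <- dim(W)
  if (xd[4] != wd[4])
    stop("channel mismatch: input has ", xd[4], ", kernel expects ", wd[4])
  y <- cpp_conv3d_fwd(as.vector(x), xd, as.vector(W), wd, b)
  array(y, c(xd[1:3], wd[5]))
}

inorm_fwd <- function(x, g, beta) {
  xd <- dim(x)
  n <- prod(xd[1:3])
  xm <- matrix(x, n, xd[4])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  istd <- 1 / sqrt(colMeans(xc^2) + IN_EPS)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, g, `*`), 2, beta, `+`)
  list(y = array(y, xd), cache = list(xhat = xhat, istd = istd, dim = xd))
}

inorm_bwd <- function(dy, g, cache) {
  xd <- cache$dim
  n <- prod(xd[1:3])
  dym <- matrix(dy, n, xd[4])
  xhat <- cache$xhat
  dg <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, g, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- sweep(dxhat, 2, s1 / n) - sweep(xhat, 2, s2 / n, `*`)
  dx <- sweep(dx, 2, cache$istd, `*`)
  list(dx = array(dx, xd), dg = dg, dbeta = dbeta)
}

lrelu_fwd <- function(x) {
  pos <- x > 0
  list(y = x * (LRELU_SLOPE + (1 - LRELU_SLOPE) * pos), cache = pos)
}

lrelu_bwd <- function(dy, pos) dy * (LRELU_SLOPE + (1 - LRELU_SLOPE) * pos)

# composite operator forward; cache = per-stage intermediates
op_fwd <- function(op, x, keep_cache = FALSE) {
  x <- as_feature4(x)
  caches <- if (keep_cache) vector("list", length(op$stages)) else NULL
  h <- x
  for (i in seq_along(op$stages)) {
    st <- op$stages[[i]]
    xin <- h
    h <- conv_fwd(h, st$W, st$b)
    inr <- inorm_fwd(h, st$g, st$beta)
    lr <- lrelu_fwd(inr$y)
    h <- lr$y
    if (keep_cache)
      caches[[i]] <- list(xin = xin, inorm = inr$cache, pos = lr$cache)
  }
  list(y = h, cache = caches)
}

op_bwd <- function(op, cache, dy) {
  grads <- vector("list", length(op$stages))
  for (i in rev(seq_along(op$stages))) {
    st <- op$stages[[i]]
    ca <- cache[[i]]
    dy <- lrelu_bwd(dy, ca$pos)
    ib <- inorm_bwd(dy, st$g, ca$inorm)
    cb <- cpp_conv3d_bwd(as.vector(ca$xin), dim(ca$xin), as.vector(st$W),
                         dim(st$W), as.vector(ib$dx))
    grads[[i]] <- list(W = array(cb$dw, dim(st$W)), b = cb$db,
                       g = ib$dg, beta = ib$dbeta)
    dy <- array(cb$dx, dim(ca$xin))
  }
  list(dx = dy, stages = grads)
}

#' Softmax architecture weights
#'
#' Converts the learnable per-block logits of the architecture search
#' into operator weights: `gamma_k = exp(alpha_k) / sum_m exp(alpha_m)`,
#' computed with max-logit subtraction for numerical stability.
#'
#' @param alphas numeric vector of finite logits (length 6 for the
#'   standard operator space, but any length is accepted).
#' @return weights summing to 1, all strictly positive.
#' @examples
#' gamma_weights(c(0, 0, 0, 0, 0, 0))
#' @export
gamma_weights <- function(alphas) {
  if (!is.numeric(alphas) || any(!is.finite(alphas)))
    stop("logits must be finite numeric values")
  e <- exp(alphas - max(alphas))
  e / sum(e)
}

#' Weighted mixture of candidate operators
#'
#' The continuous relaxation of the architecture choice: the block
#' output is the convex combination `sum_k weights_k * op_k(input)` of
#' all candidate operator outputs.
#'
#' @param input feature array, dim (nz, ny, nx, channels) (a 3D array
#'   is treated as single-channel).
#' @param ops list of `"conv_op"` candidates sharing input/output
#'   channel counts.
#' @param weights numeric weights, typically from [gamma_weights()].
#' @return the mixed feature array; spatial shape equals the input's.
#' @export
mixed_block_forward <- function(input, ops, weights) {
  stopifnot(length(ops) == length(weights))
  input <- as_feature4(input)
  out <- NULL
  for (k in seq_along(ops)) {
    yk <- op_fwd(ops[[k]], input)$y
    if (is.null(out)) out <- weights[k] * yk
    else {
      if (!identical(dim(out), dim(yk)))
        stop("candidate outputs disagree in shape: ",
             paste(dim(out), collapse = "x"), " vs ",
             paste(dim(yk), collapse = "x"))
      out <- out + weights[k] * yk
    }
  }
  out
}

# mixed block with caches for the search backward pass
mixed_fwd <- function(ops, alphas, x, keep_cache = FALSE) {
  x <- as_feature4(x)
  gam <- gamma_weights(alphas)
  outs <- vector("list", length(ops))
  caches <- if (keep_cache) vector("list", length(ops)) else NULL
  y <- NULL
  for (k in seq_along(ops)) {
    fk <- op_fwd(ops[[k]], x, keep_cache)
    outs[[k]] <- fk$y
    if (keep_cache) caches[[k]] <- fk$cache
    y <- if (is.null(y)) gam[k] * fk$y else y + gam[k] * fk$y
  }
  list(y = y, cache = list(op_caches = caches, outs = outs, gam = gam))
}

mixed_bwd <- function(ops, cache, dy) {
  gam <- cache$gam
  K <- length(ops)
  dx <- NULL
  op_grads <- vector("list", K)
  gdot <- numeric(K)  # <dy, op_k(x)>
  for (k in seq_len(K)) {
    gdot[k] <- sum(dy * cache$outs[[k]])
    bk <- op_bwd(ops[[k]], cache$op_caches[[k]], gam[k] * dy)
    op_grads[[k]] <- bk$stages
    dx <- if (is.null(dx)) bk$dx else dx + bk$dx
  }
  dalpha <- gam * (gdot - sum(gam * gdot))
  list(dx = dx, op_grads = op_grads, dalpha = dalpha)
}

# ---- generic parameter-tree utilities (used by the Adam optimizer) ----

ptree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- ptree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

ptree_zero_like <- function(a) {
  if (is.list(a)) lapply(a, ptree_zero_like)
  else {
    z <- a; z[] <- 0; z
  }
}

adam_init <- function(params)
  list(m = ptree_zero_like(params), v = ptree_zero_like(params), t = 0L)

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- ptree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- ptree_map2(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  mh <- 1 / (1 - b1^state$t)
  vh <- 1 / (1 - b2^state$t)
  upd <- ptree_map2(function(m, v) lr * (m * mh) / (sqrt(v * vh) + eps),
                    state$m, state$v)
  params <- ptree_map2(`-`, params, upd)
  list(params = params, state = state)
}
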