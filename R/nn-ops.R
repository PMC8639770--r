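# Minimal CNN engine on base R + BLAS.
#
# Activations are numeric arrays [H, W, C, N]. Convolutions run as
# im2col + GEMM; the gather/scatter index tables are cached per shape.
# All operations have exact analytic backward passes, so training is
# bit-reproducible given the seed.

.nn_cache <- new.env(parent = emptyenv())

# Index table mapping im2col rows/cols into the zero-padded input volume.
# Rows iterate (kr, kc, ch) with kr fastest -- conv weights use the same
# order. Columns iterate (out_row, out_col, sample).
im2col_index <- function(h, w, ch, n, k, stride, pad) {
  key <- paste(h, w, ch, n, k, stride, pad, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  oh <- (hp - k) %/% stride + 1L
  ow <- (wp - k) %/% stride + 1L
  kr <- rep(seq_len(k), times = k * ch)
  kc <- rep(rep(seq_len(k), each = k), times = ch)
  kch <- rep(seq_len(ch), each = k * k)
  or_ <- rep(seq_len(oh), times = ow)
  oc_ <- rep(seq_len(ow), each = oh)
  # linear index into [hp, wp, ch] for one sample
  base_r <- outer(kr, (or_ - 1L) * stride, `+`)              # (kkc, ohow)
  base_c <- outer(kc, (oc_ - 1L) * stride, `+`)
  idx1 <- base_r + (base_c - 1L) * hp + (kch - 1L) * hp * wp
  vol <- hp * wp * ch
  idx <- matrix(0L, nrow(idx1), ncol(idx1) * n)
  for (s in seq_len(n))
    idx[, ((s - 1L) * ncol(idx1) + 1L):(s * ncol(idx1))] <-
      idx1 + (s - 1L) * vol
  storage.mode(idx) <- "integer"
  out <- list(idx = as.vector(idx), nrow = nrow(idx), oh = oh, ow = ow,
              hp = hp, wp = wp)
  .nn_cache[[key]] <- out
  out
}

pad_input <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(value, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), , ] <- x
  xp
}

# Forward convolution. w is (c_out, k*k*c_in); no bias (batch norm follows).
conv_forward <- function(x, w, k, stride, pad) {
  d <- dim(x)
  ix <- im2col_index(d[1], d[2], d[3], d[4], k, stride, pad)
  xp <- pad_input(x, pad)
  cols <- matrix(xp[ix$idx], nrow = ix$nrow)
  y <- w %*% cols                                     # (c_out, ohow*n)
  c_out <- nrow(w)
  yarr <- aperm(array(y, c(c_out, ix$oh, ix$ow, d[4])), c(2, 3, 1, 4))
  list(y = yarr, cols = cols, in_dim = d, k = k, stride = stride, pad = pad)
}

conv_backward <- function(cache, w, dy) {
  d <- cache$in_dim
  ix <- im2col_index(d[1], d[2], d[3], d[4], cache$k, cache$stride, cache$pad)
  c_out <- nrow(w)
  dym <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = c_out)
  dw <- tcrossprod(dym, cache$cols)
  dcols <- crossprod(w, dym)
  dxp <- numeric(ix$hp * ix$wp * d[3] * d[4])
  scatter_add(dxp, ix$idx, dcols)
  dxp <- array(dxp, c(ix$hp, ix$wp, d[3], d[4]))
  p <- cache$pad
  dx <- if (p > 0L) dxp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ,
                        drop = FALSE] else dxp
  list(dx = dx, dw = dw)
}

# Batch normalization over (H, W, N) per channel. Training mode uses batch
# statistics and updates running estimates (momentum 0.1, unbiased variance
# for the running update); eval mode uses the running estimates.
bn_forward <- function(x, gamma, beta, rm, rv, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])   # (HWN, C)
  if (training) {
    mu <- colMeans(m)
    ctr <- sweep(m, 2, mu)
    var_b <- colMeans(ctr * ctr)
    nn <- nrow(m)
    rm_new <- (1 - momentum) * rm + momentum * mu
    rv_new <- (1 - momentum) * rv + momentum * var_b * nn / max(nn - 1, 1)
    invstd <- 1 / sqrt(var_b + eps)
    xhat <- sweep(ctr, 2, invstd, `*`)
  } else {
    invstd <- 1 / sqrt(rv + eps)
    xhat <- sweep(sweep(m, 2, rm), 2, invstd, `*`)
    rm_new <- rm; rv_new <- rv
  }
  ym <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  y <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(y = y, xhat = xhat, invstd = invstd, dim = d,
       rm = rm_new, rv = rv_new)
}

bn_backward <- function(cache, gamma, dy) {
  d <- cache$dim
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = d[3])
  nn <- nrow(dym)
  dbeta <- colSums(dym)
  dgamma <- colSums(dym * cache$xhat)
  # dX = gamma * invstd / n * (n*dY - sum(dY) - xhat * sum(dY*xhat))
  t1 <- sweep(dym, 2, dbeta / nn)
  t2 <- sweep(cache$xhat, 2, dgamma / nn, `*`)
  dxm <- sweep(t1 - t2, 2, gamma * cache$invstd, `*`)
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) pmax(x, 0)
relu_backward <- function(x, dy) dy * (x > 0)

# 3x3 stride-2 max pooling with padding 1 (-Inf fill), per channel.
maxpool_forward <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  x2 <- array(x, c(d[1], d[2], 1L, d[3] * d[4]))
  ix <- im2col_index(d[1], d[2], 1L, d[3] * d[4], k, stride, pad)
  xp <- pad_input(x2, pad, value = -Inf)
  cols <- matrix(xp[ix$idx], nrow = k * k)
  ymax <- cols[1, ]
  amax <- rep(1L, ncol(cols))
  for (r in 2:(k * k)) {
    upd <- cols[r, ] > ymax
    ymax[upd] <- cols[r, upd]
    amax[upd] <- r
  }
  y <- array(ymax, c(ix$oh, ix$ow, d[3], d[4]))
  list(y = y, amax = amax, in_dim = d, k = k, stride = stride, pad = pad)
}

maxpool_backward <- function(cache, dy) {
  d <- cache$in_dim
  k <- cache$k
  ix <- im2col_index(d[1], d[2], 1L, d[3] * d[4], k, cache$stride, cache$pad)
  dxp <- numeric(ix$hp * ix$wp * d[3] * d[4])
  dyv <- as.vector(dy)
  m <- length(dyv)
  targets <- ix$idx[cache$amax + (seq_len(m) - 1L) * (k * k)]
  scatter_add(dxp, targets, dyv)
  dxp <- array(dxp, c(ix$hp, ix$wp, d[3], d[4]))
  p <- cache$pad
  if (p > 0L) dxp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ,
                  drop = FALSE] else dxp
}

# Global average pooling [H,W,C,N] -> (C, N)
gap_forward <- function(x) {
  d <- dim(x)
  y <- matrix(0, d[3], d[4])
  hw <- d[1] * d[2]
  for (s in seq_len(d[4]))
    y[, s] <- colMeans(matrix(x[, , , s], nrow = hw))
  y
}

gap_backward <- function(in_dim, dy) {
  hw <- in_dim[1] * in_dim[2]
  dx <- array(0, in_dim)
  for (s in seq_len(in_dim[4]))
    dx[, , , s] <- array(rep(dy[, s], each = hw) / hw, in_dim[1:3])
  dx
}

# Binary cross-entropy with logits (numerically stable) and its gradient.
bce_with_logits <- function(logits, y) {
  z <- logits
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  grad <- (stats::plogis(z) - y) / length(y)
  list(loss = loss, grad = grad)
}

# Elementwise tree utilities over nested parameter lists ---------------------

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[i] <- list(tree_map(f, a[[i]]))
    out
  } else if (is.null(a)) NULL else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[i] <- list(tree_map2(f, a[[i]], b[[i]]))
    out
  } else if (is.null(a)) NULL else f(a, b)
}

tree_sum <- function(f, a) {
  if (is.list(a)) sum(vapply(a, function(el) tree_sum(f, el), numeric(1)))
  else if (is.null(a)) 0 else f(a)
}

# One Adam step over a parameter tree. params, m and v are updated IN PLACE
# (compiled kernel); callers must deep-copy any state they snapshot (see
# tree_copy), which cnn_train does for its checkpoints.
adam_step <- function(params, grads, m, v, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  walk <- function(p, g, mm, vv) {
    if (is.list(p)) {
      for (i in seq_along(p))
        if (!is.null(p[[i]])) walk(p[[i]], g[[i]], mm[[i]], vv[[i]])
    } else {
      adam_update_leaf(p, mm, vv, g, lr, bc1, bc2, beta1, beta2, eps)
    }
  }
  walk(params, grads, m, v)
  invisible(list(params = params, m = m, v = v))
}

# Deep copy of a parameter tree (forces fresh allocations, so in-place
# optimizer updates cannot reach the copy).
tree_copy <- function(a) tree_map(function(x) x + 0, a)
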