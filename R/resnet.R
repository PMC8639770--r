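# 18-layer residual network (ResNet-18) with a single-logit head for binary
# focus classification: 7x7/2 stem convolution, 3x3/2 max pool, four stages
# of two basic residual blocks (64/128/256/512 channels, stride-2 entry from
# stage 2 on), global average pooling and one fully connected output unit.
# Every convolution is followed by batch normalization; convolutions carry
# no bias.

.resnet_stages <- list(channels = c(64L, 128L, 256L, 512L),
                       blocks = c(2L, 2L, 2L, 2L),
                       stride = c(1L, 2L, 2L, 2L))

conv_init <- function(c_out, c_in, k) {
  # Kaiming-normal, fan_out mode (k*k*c_out), the convention for residual nets
  sd <- sqrt(2 / (k * k * c_out))
  matrix(stats::rnorm(c_out * k * k * c_in, 0, sd), nrow = c_out)
}

bn_init <- function(ch) list(g = rep(1, ch), b = rep(0, ch))
bn_stats_init <- function(ch) list(rm = rep(0, ch), rv = rep(1, ch))

#' Build a randomly initialized ResNet-18 focus classifier
#'
#' Constructs the 18-layer residual network with a single-logit sigmoid head.
#' Initialization is seeded (Kaiming-normal convolutions, unit-gain batch
#' norm); two builds with the same seed have identical parameters.
#'
#' @param pretrained must be `FALSE`; the training protocol trains from
#'   scratch and no pretrained weights ship with the package.
#' @param seed integer seed for the initialization.
#' @return object of class `resnet18` with elements `params`, `stats`
#'   (batch-norm running estimates) and `n_params`.
#' @export
build_model <- function(pretrained = FALSE, seed = 0L) {
  if (isTRUE(pretrained))
    stopf("pretrained weights are not available; the protocol trains from scratch")
  with_seed(seed, {
    params <- list(stem = c(list(w = conv_init(64L, 3L, 7L)), bn_init(64L)),
                   layers = list(), fc = NULL)
    stats <- list(stem = bn_stats_init(64L), layers = list())
    c_in <- 64L
    for (st in 1:4) {
      ch <- .resnet_stages$channels[st]
      blocks <- vector("list", .resnet_stages$blocks[st])
      bstats <- vector("list", .resnet_stages$blocks[st])
      for (bl in seq_len(.resnet_stages$blocks[st])) {
        s <- if (bl == 1L) .resnet_stages$stride[st] else 1L
        need_down <- (s != 1L) || (c_in != ch)
        blk <- list(w1 = conv_init(ch, c_in, 3L))
        blk <- c(blk, stats::setNames(bn_init(ch), c("g1", "b1")))
        blk$w2 <- conv_init(ch, ch, 3L)
        blk <- c(blk, stats::setNames(bn_init(ch), c("g2", "b2")))
        if (need_down) {
          blk$wd <- conv_init(ch, c_in, 1L)
          blk <- c(blk, stats::setNames(bn_init(ch), c("gd", "bd")))
        }
        blocks[[bl]] <- blk
        bs <- c(stats::setNames(bn_stats_init(ch), c("rm1", "rv1")),
                stats::setNames(bn_stats_init(ch), c("rm2", "rv2")))
        if (need_down)
          bs <- c(bs, stats::setNames(bn_stats_init(ch), c("rmd", "rvd")))
        bstats[[bl]] <- bs
        c_in <- ch
      }
      params$layers[[st]] <- blocks
      stats$layers[[st]] <- bstats
    }
    fan_in <- 512L
    bound <- 1 / sqrt(fan_in)
    params$fc <- list(w = matrix(stats::runif(fan_in, -bound, bound), nrow = 1),
                      b = stats::runif(1, -bound, bound))
    n_params <- tree_sum(length, params)
    structure(list(params = params, stats = stats, n_params = n_params),
              class = "resnet18")
  })
}

#' @export
print.resnet18 <- function(x, ...) {
  cat(sprintf("<resnet18> 18-layer residual network, single-logit head, %s parameters\n",
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

block_stride <- function(stage, block_idx) {
  if (block_idx == 1L) .resnet_stages$stride[stage] else 1L
}

# Forward pass. x: [H, W, 3, N] normalized input. Returns logits (length N),
# the updated running stats and, when `keep_cache`, everything the backward
# pass needs.
resnet_forward <- function(params, stats, x, training = FALSE,
                           keep_cache = FALSE) {
  cache <- if (keep_cache) list() else NULL
  cs <- conv_forward(x, params$stem$w, 7L, 2L, 3L)
  bs <- bn_forward(cs$y, params$stem$g, params$stem$b,
                   stats$stem$rm, stats$stem$rv, training)
  stats$stem$rm <- bs$rm; stats$stem$rv <- bs$rv
  r <- relu_forward(bs$y)
  mp <- maxpool_forward(r)
  h <- mp$y
  if (keep_cache) cache$stem <- list(conv = cs, bn = bs, pre_relu = bs$y, mp = mp)
  for (st in 1:4) {
    for (bl in seq_along(params$layers[[st]])) {
      p <- params$layers[[st]][[bl]]
      s <- stats$layers[[st]][[bl]]
      stride <- block_stride(st, bl)
      c1 <- conv_forward(h, p$w1, 3L, stride, 1L)
      b1 <- bn_forward(c1$y, p$g1, p$b1, s$rm1, s$rv1, training)
      r1 <- relu_forward(b1$y)
      c2 <- conv_forward(r1, p$w2, 3L, 1L, 1L)
      b2 <- bn_forward(c2$y, p$g2, p$b2, s$rm2, s$rv2, training)
      if (!is.null(p$wd)) {
        cd <- conv_forward(h, p$wd, 1L, stride, 0L)
        bd <- bn_forward(cd$y, p$gd, p$bd, s$rmd, s$rvd, training)
        short <- bd$y
        s$rmd <- bd$rm; s$rvd <- bd$rv
      } else { cd <- NULL; bd <- NULL; short <- h }
      s$rm1 <- b1$rm; s$rv1 <- b1$rv; s$rm2 <- b2$rm; s$rv2 <- b2$rv
      stats$layers[[st]][[bl]] <- s
      pre <- b2$y + short
      out <- relu_forward(pre)
      if (keep_cache)
        cache[[paste0("s", st, "b", bl)]] <-
          list(c1 = c1, b1 = b1, pre1 = b1$y, c2 = c2, b2 = b2,
               cd = cd, bd = bd, pre = pre)
      h <- out
    }
  }
  feat <- gap_forward(h)                      # (512, N)
  logits <- drop(params$fc$w %*% feat + params$fc$b)
  if (keep_cache) {
    cache$feat <- feat
    cache$head_in_dim <- dim(h)
  }
  list(logits = logits, stats = stats, cache = cache)
}

# Backward pass from dlogits (length N); returns gradients shaped as params.
resnet_backward <- function(params, cache, dlogits) {
  grads <- list(stem = list(w = NULL, g = NULL, b = NULL), layers = list(),
                fc = list(w = NULL, b = NULL))
  dlog <- matrix(dlogits, nrow = 1)
  grads$fc$w <- tcrossprod(dlog, cache$feat)
  grads$fc$b <- sum(dlog)
  dfeat <- crossprod(params$fc$w, dlog)       # (512, N)
  dh <- gap_backward(cache$head_in_dim, dfeat)
  for (st in 4:1) {
    grads$layers[[st]] <- vector("list", length(params$layers[[st]]))
    for (bl in rev(seq_along(params$layers[[st]]))) {
      p <- params$layers[[st]][[bl]]
      cc <- cache[[paste0("s", st, "b", bl)]]
      dpre <- relu_backward(cc$pre, dh)
      # shortcut branch
      if (!is.null(p$wd)) {
        bwd <- bn_backward(cc$bd, p$gd, dpre)
        cvd <- conv_backward(cc$cd, p$wd, bwd$dx)
        dshort <- cvd$dx
        gd <- bwd$dgamma; bd_ <- bwd$dbeta; wd <- cvd$dw
      } else { dshort <- dpre; gd <- NULL; bd_ <- NULL; wd <- NULL }
      # main branch
      bw2 <- bn_backward(cc$b2, p$g2, dpre)
      cv2 <- conv_backward(cc$c2, p$w2, bw2$dx)
      dr1 <- relu_backward(cc$pre1, cv2$dx)
      bw1 <- bn_backward(cc$b1, p$g1, dr1)
      cv1 <- conv_backward(cc$c1, p$w1, bw1$dx)
      dh <- cv1$dx + dshort
      g <- list(w1 = cv1$dw, g1 = bw1$dgamma, b1 = bw1$dbeta,
                w2 = cv2$dw, g2 = bw2$dgamma, b2 = bw2$dbeta)
      if (!is.null(wd)) { g$wd <- wd; g$gd <- gd; g$bd <- bd_ }
      grads$layers[[st]][[bl]] <- g
    }
  }
  dmp <- maxpool_backward(cache$stem$mp, dh)
  drelu <- relu_backward(cache$stem$pre_relu, dmp)
  bws <- bn_backward(cache$stem$bn, params$stem$g, drelu)
  cvs <- conv_backward(cache$stem$conv, params$stem$w, bws$dx)
  grads$stem <- list(w = cvs$dw, g = bws$dgamma, b = bws$dbeta)
  grads
}
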