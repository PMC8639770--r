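# Internal helpers: seeded evaluation, image array utilities, geometry.
# Images are numeric arrays [height, width, 3] with values in [0, 255],
# row-major, origin at the top-left pixel.

# Evaluate `expr` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = TRUE))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Convert an RGB image array to 8-bit grayscale
#'
#' Uses the Rec. 601 luma transform `0.299 R + 0.587 G + 0.114 B`, rounded
#' to the nearest integer.
#'
#' @param pixels numeric array `[h, w, 3]` with values in `[0, 255]`.
#' @return integer matrix `[h, w]` of gray levels in `0..255`.
#' @export
rgb_to_gray <- function(pixels) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  g <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  matrix(as.integer(round(g)), nrow = dim(pixels)[1])
}

#' HSV saturation channel quantized to 0..255
#'
#' Converts an RGB image to HSV (via [grDevices::rgb2hsv()]) and returns the
#' saturation channel mapped to integers in `0..255`, the histogram domain
#' used by discriminant-analysis thresholding.
#'
#' @inheritParams rgb_to_gray
#' @return integer matrix `[h, w]` with values in `0..255`.
#' @export
saturation_u8 <- function(pixels) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  m <- rbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
             as.vector(pixels[, , 3]))
  s <- grDevices::rgb2hsv(m, maxColorValue = 255)["s", ]
  matrix(as.integer(round(s * 255)), nrow = h)
}

# Bilinear sample of a single-channel matrix at fractional (row, col)
# coordinates; out-of-range coordinates return `fill`.
bilinear_sample <- function(m, rs, cs, fill) {
  h <- nrow(m); w <- ncol(m)
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0; fc <- cs - c0
  out <- numeric(length(rs))
  acc <- numeric(length(rs))
  wt_tot <- numeric(length(rs))
  for (dr in 0:1) for (dc in 0:1) {
    rr <- r0 + dr; cc <- c0 + dc
    wt <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w & wt > 0
    if (any(ok)) {
      acc[ok] <- acc[ok] + wt[ok] * m[cbind(rr[ok], cc[ok])]
      wt_tot[ok] <- wt_tot[ok] + wt[ok]
    }
  }
  # Pixels whose 4-neighbourhood falls partly outside blend with the fill
  out <- acc + (1 - wt_tot) * fill
  inside <- rs >= 0.5 & rs <= h + 0.5 & cs >= 0.5 & cs <= w + 0.5
  out[!inside] <- fill
  out
}

#' Resize an RGB image with bilinear interpolation
#'
#' @param pixels numeric array `[h, w, 3]`.
#' @param out_h,out_w target size in pixels.
#' @return numeric array `[out_h, out_w, 3]`.
#' @export
resize_bilinear <- function(pixels, out_h, out_w) {
  d <- dim(pixels)
  if (d[1] == out_h && d[2] == out_w) return(pixels)
  sr <- d[1] / out_h; sc <- d[2] / out_w
  rs <- ( (seq_len(out_h) - 0.5) * sr ) + 0.5
  cs <- ( (seq_len(out_w) - 0.5) * sc ) + 0.5
  rs <- clamp(rs, 1, d[1]); cs <- clamp(cs, 1, d[2])
  grid_r <- rep(rs, times = out_w)
  grid_c <- rep(cs, each = out_h)
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- matrix(bilinear_sample(pixels[, , ch], grid_r, grid_c, 0),
                          nrow = out_h)
  }
  out
}

# Median color of the 1-pixel image border, per channel (used as the
# constant fill for affine augmentation).
border_median_color <- function(pixels) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  idx <- rbind(cbind(1L, seq_len(w)), cbind(h, seq_len(w)),
               cbind(seq_len(h), 1L), cbind(seq_len(h), w))
  vapply(seq_len(dim(pixels)[3]),
         function(ch) stats::median(pixels[, , ch][idx]), numeric(1))
}

# Affine warp of an RGB image. The forward map acts on (x, y) = (col, row)
# coordinates about the image center: rotation by `angle` degrees, x-shear by
# `shear` degrees, then translation by (tx, ty) pixels. Inverse-mapped with
# bilinear interpolation; `fill` is the per-channel constant background.
warp_affine <- function(pixels, angle = 0, shear = 0, tx = 0, ty = 0,
                        fill = NULL) {
  if (angle == 0 && shear == 0 && tx == 0 && ty == 0) return(pixels)
  d <- dim(pixels)
  if (is.null(fill)) fill <- border_median_color(pixels)
  th <- angle * pi / 180
  sh <- tan(shear * pi / 180)
  # forward: p' = C + t + R %*% S %*% (p - C); invert analytically
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  S <- matrix(c(1, 0, sh, 1), 2)
  A <- R %*% S
  Ainv <- solve(A)
  cx <- (d[2] + 1) / 2; cy <- (d[1] + 1) / 2
  xo <- rep(seq_len(d[2]), each = d[1]) - cx - tx
  yo <- rep(seq_len(d[1]), times = d[2]) - cy - ty
  xs <- Ainv[1, 1] * xo + Ainv[1, 2] * yo + cx
  ys <- Ainv[2, 1] * xo + Ainv[2, 2] * yo + cy
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    out[, , ch] <- matrix(bilinear_sample(pixels[, , ch], ys, xs, fill[ch]),
                          nrow = d[1])
  }
  out
}

flip_horizontal <- function(pixels) pixels[, rev(seq_len(dim(pixels)[2])), , drop = FALSE]
flip_vertical   <- function(pixels) pixels[rev(seq_len(dim(pixels)[1])), , , drop = FALSE]
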