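# Synthetic Giemsa-like focus-candidate image generator.
#
# Positive phenotypes encode the six OECD morphological criteria for a
# transformed focus: basophilic (dark, saturated Giemsa stain), spindle-shaped
# cells (high aspect ratio), multilayered (dense, overlapping cells), random
# orientation, invasive (irregular) border, and >= 100 cells. Negatives
# violate one randomly chosen criterion among {cell count, stain intensity,
# border irregularity}; the violated criterion is recorded so feature
# ablations are testable.

# Style registry: per-style, per-label parameter ranges. Ranges are uniform
# [lo, hi]; cluster radius is derived from cell count and areal density.
.style_registry <- list(
  "TPA-like" = list(
    cell_scale = 1.0,
    pos = list(cell_count = c(140, 300), elongation = c(2.5, 4.0),
               orientation_dispersion = c(60, 90), stain_intensity = c(0.65, 0.90),
               density = c(0.010, 0.016), border_irregularity = c(0.5, 0.9)),
    neg_low = list(cell_count = c(20, 80), stain_intensity = c(0.10, 0.30),
                   border_irregularity = c(0.0, 0.08))
  ),
  "micro-focus" = list(
    cell_scale = 0.8,
    pos = list(cell_count = c(100, 160), elongation = c(2.5, 4.0),
               orientation_dispersion = c(60, 90), stain_intensity = c(0.70, 0.92),
               density = c(0.030, 0.045), border_irregularity = c(0.5, 0.9)),
    neg_low = list(cell_count = c(20, 80), stain_intensity = c(0.10, 0.30),
                   border_irregularity = c(0.0, 0.08))
  ),
  "LCA-like" = list(
    cell_scale = 1.1,
    pos = list(cell_count = c(260, 420), elongation = c(2.5, 4.0),
               orientation_dispersion = c(60, 90), stain_intensity = c(0.75, 0.95),
               density = c(0.010, 0.014), border_irregularity = c(0.5, 0.9)),
    neg_low = list(cell_count = c(20, 80), stain_intensity = c(0.10, 0.30),
                   border_irregularity = c(0.0, 0.08))
  )
)

#' Registered chemical styles of the synthetic generator
#' @return character vector of style names.
#' @export
focus_styles <- function() names(.style_registry)

.get_style <- function(style) {
  if (!style %in% names(.style_registry))
    stopf("unknown style '%s'; registered styles: %s", style,
          paste(names(.style_registry), collapse = ", "))
  .style_registry[[style]]
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Sample a focus phenotype
#'
#' Draws the morphological parameters of one focus candidate from the
#' style's distributions. Positive phenotypes satisfy all six transformed-
#' focus criteria (in particular `cell_count >= 100`); negative phenotypes
#' start from the positive distribution and violate one randomly chosen
#' criterion among cell count, stain intensity and border irregularity
#' (recorded in `$violated`).
#'
#' @param label 0/1 (or "negative"/"positive").
#' @param style one of [focus_styles()]; styles differ in focus size and
#'   stain distributions (e.g. `"micro-focus"` emulates small microfoci).
#' @param rng_seed integer seed; the draw is a pure function of
#'   `(label, style, rng_seed, contrast)`.
#' @param contrast inter-class contrast dial in `[0, 1]`. At 1 the violated
#'   criterion is drawn from its fully "benign" range; at 0 negatives are
#'   drawn from the positive distribution (labels carry no signal).
#' @return an object of class `focus_phenotype`.
#' @export
sample_phenotype <- function(label, style = "TPA-like", rng_seed = 0L,
                             contrast = 1) {
  lab <- normalize_label(label)
  sty <- .get_style(style)
  stopifnot(contrast >= 0, contrast <= 1)
  with_seed(rng_seed, {
    p <- sty$pos
    ph <- list(
      label = lab, style = style,
      cell_count = as.integer(round(runif1(p$cell_count))),
      elongation = runif1(p$elongation),
      orientation_dispersion = runif1(p$orientation_dispersion),
      stain_intensity = runif1(p$stain_intensity),
      density = runif1(p$density),
      border_irregularity = runif1(p$border_irregularity),
      cell_scale = sty$cell_scale,
      violated = NA_character_
    )
    if (lab == 0L) {
      crit <- sample(c("cell_count", "stain_intensity", "border_irregularity"), 1)
      low <- runif1(sty$neg_low[[crit]])
      # interpolate toward the positive draw as contrast decreases
      v <- contrast * low + (1 - contrast) * ph[[crit]]
      ph[[crit]] <- if (crit == "cell_count") as.integer(round(v)) else v
      ph$violated <- crit
    }
    ph$cluster_radius <- clamp(sqrt(ph$cell_count / (pi * ph$density)), 15, 220)
    structure(ph, class = "focus_phenotype")
  })
}

normalize_label <- function(label) {
  if (is.character(label))
    label <- switch(tolower(label), positive = 1L, negative = 0L,
                    stopf("label must be 0/1 or 'positive'/'negative'"))
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stopf("label must be 0 or 1")
  label
}

#' @export
print.focus_phenotype <- function(x, ...) {
  cat(sprintf("<focus_phenotype> label=%d style=%s cells=%d radius=%.1fpx stain=%.2f irregularity=%.2f%s\n",
              x$label, x$style, x$cell_count, x$cluster_radius,
              x$stain_intensity, x$border_irregularity,
              if (is.na(x$violated)) "" else paste0(" violated=", x$violated)))
  invisible(x)
}

# Giemsa-like deep blue-purple stain color (RGB, 0..255)
.stain_color <- c(78, 52, 122)

# Radial boundary perturbation of the cluster: 1 + irregularity * sum of
# low-order Fourier modes, so irregularity 0 gives an exact disk.
.boundary_modes <- function(irregularity) {
  ks <- 4:16
  amp <- irregularity * 0.5 * (0.7 + 0.6 * stats::runif(length(ks))) / ks
  amp <- amp * sample(c(-1, 1), length(ks), replace = TRUE)
  phi <- stats::runif(length(ks), 0, 2 * pi)
  list(ks = ks, amp = amp, phi = phi)
}

.boundary_rho <- function(theta, radius, modes) {
  pert <- rep(0, length(theta))
  for (i in seq_along(modes$ks))
    pert <- pert + modes$amp[i] * cos(modes$ks[i] * theta + modes$phi[i])
  radius * pmax(0.4, 1 + pert)
}

#' Render a synthetic focus-candidate micrograph
#'
#' Draws a light, low-saturation monolayer background and a central cluster
#' of elongated elliptical "cells" in a jittered Giemsa blue-purple, composed
#' over a soft basophilic cluster tint whose darkness and saturation scale
#' with `stain_intensity`. The ground-truth cluster mask is attached as
#' attribute `"truth_mask"`. Deterministic given `(phenotype, canvas,
#' rng_seed)`.
#'
#' @param phenotype a [sample_phenotype()] result.
#' @param canvas `(height, width)`, both >= 224.
#' @param rng_seed integer seed.
#' @return an object of class `focus_image` (fields `pixels`, `label`,
#'   `chemical`, `source`, `id`).
#' @export
render_image <- function(phenotype, canvas = c(512L, 512L), rng_seed = 0L) {
  stopifnot(inherits(phenotype, "focus_phenotype"))
  canvas <- as.integer(canvas)
  if (length(canvas) != 2L || any(canvas < 224L))
    stopf("canvas must be at least 224 x 224")
  h <- canvas[1]; w <- canvas[2]
  with_seed(rng_seed, {
    # -- background: light monolayer with low-amplitude smoothed noise
    bg_col <- c(234, 231, 237) + stats::runif(3, -3, 3)
    img <- array(rep(bg_col, each = h * w), c(h, w, 3))
    gh <- max(4L, h %/% 24L); gw <- max(4L, w %/% 24L)
    coarse <- matrix(stats::rnorm(gh * gw, 0, 5), gh, gw)
    noise <- resize_bilinear(array(coarse, c(gh, gw, 1)), h, w)[, , 1]
    for (ch in 1:3) img[, , ch] <- img[, , ch] + noise +
      matrix(stats::rnorm(h * w, 0, 1.2), h)

    # -- cluster geometry
    cy <- h / 2 + stats::runif(1, -0.03, 0.03) * h
    cx <- w / 2 + stats::runif(1, -0.03, 0.03) * w
    R <- min(phenotype$cluster_radius, 0.42 * min(h, w))
    modes <- .boundary_modes(phenotype$border_irregularity)
    yy <- rep(seq_len(h), times = w) - cy
    xx <- rep(seq_len(w), each = h) - cx
    theta <- atan2(yy, xx)
    rr <- sqrt(yy * yy + xx * xx)
    rho <- .boundary_rho(theta, R, modes)
    truth <- matrix(rr <= rho, h, w)
    soft <- matrix(clamp((rho + 0.75 - rr) / 1.5, 0, 1), h, w)

    # -- basophilic cluster tint (multilayer sheet), darker when stain high
    alpha <- 0.25 + 0.60 * phenotype$stain_intensity^1.2
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - alpha * soft) +
      .stain_color[ch] * alpha * soft

    # -- individual spindle cells
    n <- phenotype$cell_count
    b <- stats::runif(n, 2.2, 3.2) * phenotype$cell_scale
    a <- b * phenotype$elongation * stats::runif(n, 0.85, 1.15)
    base_angle <- stats::runif(1, 0, pi)
    ang <- base_angle + stats::rnorm(n, 0, phenotype$orientation_dispersion * pi / 180)
    u <- stats::runif(n); tpos <- stats::runif(n, 0, 2 * pi)
    rmax <- pmax(0, .boundary_rho(tpos, R, modes) - a)
    px <- cx + sqrt(u) * rmax * cos(tpos)
    py <- cy + sqrt(u) * rmax * sin(tpos)
    cell_alpha <- 0.08 + 0.70 * phenotype$stain_intensity
    for (i in seq_len(n)) {
      ai <- a[i]; bi <- b[i]
      r0 <- max(1L, floor(py[i] - ai)); r1 <- min(h, ceiling(py[i] + ai))
      c0 <- max(1L, floor(px[i] - ai)); c1 <- min(w, ceiling(px[i] + ai))
      if (r0 > r1 || c0 > c1) next
      dy <- seq(r0, r1) - py[i]; dx <- seq(c0, c1) - px[i]
      DX <- matrix(dx, nrow = length(dy), ncol = length(dx), byrow = TRUE)
      DY <- matrix(dy, nrow = length(dy), ncol = length(dx))
      ca <- cos(ang[i]); sa <- sin(ang[i])
      q <- sqrt(((DX * ca + DY * sa) / ai)^2 + ((-DX * sa + DY * ca) / bi)^2)
      cov <- clamp((1 - q) * bi + 0.5, 0, 1) * cell_alpha
      col_i <- .stain_color + stats::rnorm(3, 0, 12)
      for (ch in 1:3) {
        img[r0:r1, c0:c1, ch] <- img[r0:r1, c0:c1, ch] * (1 - cov) +
          col_i[ch] * cov
      }
    }
    img <- clamp(img, 0, 255)
    structure(list(pixels = img, label = phenotype$label,
                   chemical = phenotype$style, source = "synthetic",
                   id = sprintf("%s_%d_s%d", phenotype$style,
                                phenotype$label, as.integer(rng_seed)),
                   truth_mask = truth),
              class = "focus_image")
  })
}

#' @export
print.focus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<focus_image> %s %dx%d label=%d chemical=%s source=%s\n",
              x$id, d[1], d[2], x$label, x$chemical, x$source))
  invisible(x)
}

#' Generate a labeled synthetic dataset
#'
#' Samples phenotypes and renders images for `n_pos` positive and `n_neg`
#' negative focus candidates, mixing chemical styles by `style_mix` weights.
#' With `out_dir` set, images are written as lossless PNG and the manifest as
#' CSV (`id,path,label,chemical,split`); otherwise images are kept in memory
#' as attribute `"images"` of the manifest. Fully deterministic given the
#' arguments.
#'
#' @param n_pos,n_neg class sizes (>= 0). The defaults keep the roughly
#'   78% positive proportion of expert-scored focus-candidate collections;
#'   the tests use balanced sets.
#' @param style_mix named nonnegative weights over [focus_styles()].
#' @param rng_seed master seed.
#' @param out_dir output directory, or `NULL` for in-memory images.
#' @param canvas image size, >= 224 per side.
#' @param contrast inter-class contrast in `[0, 1]`; see [sample_phenotype()].
#' @return a `focus_manifest` data.frame with columns
#'   `id, path, label, chemical, split`.
#' @export
generate_dataset <- function(n_pos = 110L, n_neg = 30L,
                             style_mix = c("TPA-like" = 1),
                             rng_seed = 0L, out_dir = NULL,
                             canvas = c(512L, 512L), contrast = 1) {
  stopifnot(n_pos >= 0, n_neg >= 0, n_pos + n_neg > 0)
  if (is.null(names(style_mix)) || any(style_mix < 0) || sum(style_mix) <= 0)
    stopf("style_mix must be named nonnegative weights, not all zero")
  for (s in names(style_mix)) .get_style(s)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      stopf("output directory does not exist: %s", out_dir)
  }
  n <- n_pos + n_neg
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  seeds <- derive_seeds(rng_seed, 2L * n + n)
  styles <- with_seed(seeds[2L * n + 1L],
                      sample(names(style_mix), n, replace = TRUE,
                             prob = style_mix / sum(style_mix)))
  ids <- sprintf("img%04d_%s", seq_len(n), ifelse(labels == 1L, "pos", "neg"))
  images <- vector("list", n)
  paths <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ph <- sample_phenotype(labels[i], styles[i], rng_seed = seeds[2L * i - 1L],
                           contrast = contrast)
    im <- render_image(ph, canvas = canvas, rng_seed = seeds[2L * i])
    im$id <- ids[i]
    if (!is.null(out_dir)) {
      paths[i] <- file.path(out_dir, paste0(ids[i], ".png"))
      png::writePNG(im$pixels / 255, paths[i])
      im$pixels <- NULL  # free memory when writing to disk
    }
    images[[i]] <- im
  }
  man <- data.frame(id = ids, path = paths, label = labels,
                    chemical = styles, split = NA_character_,
                    stringsAsFactors = FALSE)
  class(man) <- c("focus_manifest", "data.frame")
  if (is.null(out_dir)) attr(man, "images") <- images
  if (!is.null(out_dir))
    write_manifest(man, file.path(out_dir, "manifest.csv"))
  man
}

#' Write / read a dataset manifest CSV
#'
#' The manifest is the on-disk index of a labeled image set, one row per
#' focus-candidate image with columns `id,path,label,chemical,split`.
#'
#' @param manifest a `focus_manifest` data.frame.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[, c("id", "path", "label",
                                               "chemical", "split")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character", path = "character",
                                        label = "integer",
                                        chemical = "character",
                                        split = "character"))
  if (!all(c("id", "path", "label", "chemical") %in% names(man)))
    stopf("manifest must have columns id,path,label,chemical[,split]")
  if (!"split" %in% names(man)) man$split <- NA_character_
  man$split[!nzchar(man$split) | is.na(man$split)] <- NA_character_
  if (!all(man$label %in% c(0L, 1L))) stopf("manifest labels must be 0/1")
  class(man) <- c("focus_manifest", "data.frame")
  man
}

#' Per-class record counts of a manifest
#' @param manifest a `focus_manifest`.
#' @return named integer vector `c(negative = , positive = )`.
#' @export
class_counts <- function(manifest) {
  c(negative = sum(manifest$label == 0L), positive = sum(manifest$label == 1L))
}

# Fetch decoded images for manifest rows (in-memory attribute or PNG paths).
manifest_images <- function(manifest, rows = seq_len(nrow(manifest))) {
  imgs <- attr(manifest, "images")
  lapply(rows, function(i) {
    if (!is.null(imgs) && !is.null(imgs[[i]]$pixels)) return(imgs[[i]])
    p <- manifest$path[i]
    if (is.na(p) || !file.exists(p)) stopf("image not available for id %s",
                                           manifest$id[i])
    px <- png::readPNG(p)
    if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
    structure(list(pixels = px[, , 1:3, drop = FALSE] * 255,
                   label = manifest$label[i], chemical = manifest$chemical[i],
                   source = "file", id = manifest$id[i]),
              class = "focus_image")
  })
}
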