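# Classical branch, stage 1: discriminant-analysis (Otsu) thresholding of
# HSV saturation, focus-region selection, and the three hand-crafted shape
# features MD (median grayscale), ED (equivalent diameter) and WPD (weighted
# perimeter difference).

#' Discriminant-analysis (Otsu) threshold of a 256-bin histogram
#'
#' Returns the threshold `t` (bin index, 0-based) that maximizes the
#' between-class variance of the split `{<= t} / {> t}`; ties are broken by
#' the lowest index.
#'
#' @param histogram integer vector of 256 bin counts (bins 0..255).
#' @return integer threshold in `0..254`.
#' @export
otsu_threshold <- function(histogram) {
  if (length(histogram) != 256L || any(histogram < 0))
    stopf("histogram must be 256 nonnegative counts")
  if (sum(histogram > 0) < 2L) stopf("degenerate image")
  p <- histogram / sum(histogram)
  lv <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lv)
  mu_t <- mu[256]
  w1 <- 1 - w0
  # between-class variance for split at t = 0..254
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, -Inf)[1:255]
  as.integer(which.max(sigma_b) - 1L)  # which.max takes the first maximum
}

# ---- connected components (8-connectivity), run-length union-find ----

# Label the 8-connected components of a logical matrix. Returns an integer
# matrix (0 = background) with labels 1..k in decreasing... (arbitrary) order.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  runs_row <- integer(0); runs_c0 <- integer(0); runs_c1 <- integer(0)
  row_start <- integer(h + 1L)
  for (r in seq_len(h)) {
    row_start[r] <- length(runs_row) + 1L
    v <- mask[r, ]
    if (any(v)) {
      rl <- rle(v)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      keep <- rl$values
      runs_row <- c(runs_row, rep.int(r, sum(keep)))
      runs_c0 <- c(runs_c0, starts[keep])
      runs_c1 <- c(runs_c1, ends[keep])
    }
  }
  row_start[h + 1L] <- length(runs_row) + 1L
  nrun <- length(runs_row)
  if (nrun == 0L) return(matrix(0L, h, w))
  parent <- seq_len(nrun)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in 2:h) {
    a <- row_start[r - 1L]; b <- row_start[r] - 1L      # runs in row r-1
    c0 <- row_start[r]; c1 <- row_start[r + 1L] - 1L    # runs in row r
    if (a > b || c0 > c1) next
    i <- a; j <- c0
    while (i <= b && j <= c1) {
      # 8-connectivity: column ranges touching within +/- 1
      if (runs_c1[i] + 1L >= runs_c0[j] && runs_c0[i] - 1L <= runs_c1[j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      if (runs_c1[i] < runs_c1[j]) i <- i + 1L else j <- j + 1L
    }
  }
  roots <- vapply(seq_len(nrun), find, integer(1))
  labels <- match(roots, unique(roots))
  out <- matrix(0L, h, w)
  for (k in seq_len(nrun))
    out[runs_row[k], runs_c0[k]:runs_c1[k]] <- labels[k]
  out
}

shift_logical <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Perimeter of a binary region
#'
#' Weighted boundary-configuration estimator (the common regionprops
#' convention): border pixels are classified by their local neighbourhood
#' pattern and weighted 1, `sqrt(2)` or `(1 + sqrt(2))/2` so that straight,
#' diagonal and corner boundary elements contribute their isotropically
#' corrected length.
#'
#' @param mask logical matrix, the region (`TRUE` = inside).
#' @return perimeter length in pixel units.
#' @export
region_perimeter <- function(mask) {
  mask <- mask & !is.na(mask)
  if (!any(mask)) return(0)
  eroded <- mask & shift_logical(mask, 1, 0) & shift_logical(mask, -1, 0) &
    shift_logical(mask, 0, 1) & shift_logical(mask, 0, -1)
  border <- mask & !eroded
  b <- border * 1L
  conv <- 10L * (shift_logical(border, 1, 1) + shift_logical(border, 1, -1) +
                 shift_logical(border, -1, 1) + shift_logical(border, -1, -1)) +
          2L * (shift_logical(border, 1, 0) + shift_logical(border, -1, 0) +
                shift_logical(border, 0, 1) + shift_logical(border, 0, -1)) + b
  wts <- numeric(50)
  wts[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  wts[c(21, 33) + 1] <- sqrt(2)
  wts[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  hist <- tabulate(conv[border] + 1L, nbins = 50L)
  sum(hist * wts)
}

#' Segment the focus region of a candidate image
#'
#' Converts the image to HSV, thresholds the saturation channel (quantized to
#' 0..255) with [otsu_threshold()], takes the high-saturation side as
#' foreground (the Giemsa-stained dense cells; `polarity = "low"` flips
#' this), and selects the largest 8-connected component as the focus region.
#'
#' @param image a `focus_image` or a numeric `[h, w, 3]` pixel array.
#' @param polarity `"high"` (default) or `"low"`: which side of the
#'   threshold is foreground.
#' @return an object of class `segmented_region` with fields `mask`
#'   (logical matrix of the selected component), `area_px`, `perimeter_px`,
#'   `threshold`.
#' @export
segment_focus <- function(image, polarity = c("high", "low")) {
  polarity <- match.arg(polarity)
  pixels <- if (inherits(image, "focus_image")) image$pixels else image
  sat <- saturation_u8(pixels)
  t <- otsu_threshold(tabulate(as.vector(sat) + 1L, nbins = 256L))
  fg <- if (polarity == "high") sat > t else sat <= t
  if (!any(fg))
    stop(structure(class = c("focusCTA_no_region", "error", "condition"),
                   list(message = "no focus region", call = NULL)))
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)
  mask <- lab == best
  structure(list(mask = mask, area_px = as.integer(sizes[best]),
                 perimeter_px = region_perimeter(mask),
                 threshold = t),
            class = "segmented_region")
}

#' @export
print.segmented_region <- function(x, ...) {
  cat(sprintf("<segmented_region> area=%d px^2, perimeter=%.1f px, threshold=%d\n",
              x$area_px, x$perimeter_px, x$threshold))
  invisible(x)
}

#' Fit the area scaler used by the WPD feature
#'
#' Records the minimum and maximum focus areas observed over training
#' regions; these normalize the area weight in the WPD equation.
#'
#' @param regions list of `segmented_region` objects, or a numeric vector of
#'   areas (>= 2 values).
#' @return object of class `feature_scaler` with `area_min`, `area_max`.
#' @export
fit_scaler <- function(regions) {
  areas <- if (is.numeric(regions)) regions
           else vapply(regions, function(r) as.numeric(r$area_px), numeric(1))
  if (length(areas) < 2L) stopf("need at least 2 training regions")
  if (any(areas <= 0)) stopf("region areas must be positive")
  sc <- structure(list(area_min = min(areas), area_max = max(areas)),
                  class = "feature_scaler")
  if (sc$area_min == sc$area_max)
    warning("all training areas equal; degenerate scaler (WPD weight = 0)",
            call. = FALSE)
  sc
}

#' Compute the MD / ED / WPD feature vector of a segmented region
#'
#' * `MD`: median grayscale value (Rec. 601 luma) over the region pixels.
#' * `ED`: equivalent diameter, `sqrt(4 * AREA / pi)`.
#' * `WPD`: `(FRP - EFP) * (AREA - AREA_min) / (AREA_max - AREA_min)` where
#'   `FRP` is the measured region perimeter and `EFP = pi * ED` the perimeter
#'   of the equal-area circle. The area weight is clamped to `[0, 1]` when a
#'   region's area falls outside the training extremes, and defined as 0 for
#'   a degenerate scaler (`area_min == area_max`).
#'
#' @param region a `segmented_region`.
#' @param gray_image integer matrix from [rgb_to_gray()], same shape as the
#'   region mask.
#' @param scaler a [fit_scaler()] result.
#' @return object of class `feature_vector` with fields `MD`, `ED`, `WPD`,
#'   `EFP`, `area`, `perimeter`, `fallback`.
#' @export
compute_features <- function(region, gray_image, scaler) {
  stopifnot(inherits(region, "segmented_region"),
            inherits(scaler, "feature_scaler"))
  if (!all(dim(gray_image) == dim(region$mask)))
    stopf("gray_image shape must match the region mask")
  if (region$area_px <= 0) stopf("empty region")
  md <- stats::median(gray_image[region$mask])
  area <- as.numeric(region$area_px)
  ed <- sqrt(4 * area / pi)
  efp <- pi * ed
  denom <- scaler$area_max - scaler$area_min
  wt <- if (denom <= 0) 0 else clamp((area - scaler$area_min) / denom, 0, 1)
  wpd <- (region$perimeter_px - efp) * wt
  structure(list(MD = as.numeric(md), ED = ed, WPD = wpd, EFP = efp,
                 area = area, perimeter = region$perimeter_px,
                 fallback = FALSE),
            class = "feature_vector")
}

# Feature vector assigned when no focus region segments out of an image
# (typical of faint negatives): background median gray, zero size and shape.
fallback_features <- function(gray_image) {
  structure(list(MD = as.numeric(stats::median(gray_image)), ED = 0, WPD = 0,
                 EFP = 0, area = 0, perimeter = 0, fallback = TRUE),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> MD=%.1f ED=%.2f WPD=%.2f%s\n",
              x$MD, x$ED, x$WPD, if (x$fallback) " (fallback)" else ""))
  invisible(x)
}

#' Batch feature extraction over a manifest
#'
#' Segments every image and computes the MD/ED/WPD features. If `scaler` is
#' `NULL` it is fitted on the areas of all successfully segmented regions
#' (the training convention). Images whose segmentation yields no region, or
#' that are degenerate (single-valued saturation), receive the documented
#' fallback feature vector with `fallback = 1` instead of aborting the batch.
#'
#' @param manifest a `focus_manifest`.
#' @param scaler optional prefitted [fit_scaler()]; fitted on this batch if
#'   `NULL`.
#' @param out_csv optional path; when set the feature table is written as CSV.
#' @return data.frame with columns
#'   `id,label,MD,ED,WPD,area,perimeter,threshold,fallback`, with the fitted
#'   scaler attached as attribute `"scaler"`.
#' @export
extract_features <- function(manifest, scaler = NULL, out_csv = NULL) {
  imgs <- manifest_images(manifest)
  regions <- vector("list", length(imgs))
  grays <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    grays[[i]] <- rgb_to_gray(imgs[[i]]$pixels)
    regions[[i]] <- tryCatch(segment_focus(imgs[[i]]), error = function(e) NULL)
  }
  ok <- !vapply(regions, is.null, logical(1))
  if (is.null(scaler)) {
    if (sum(ok) < 2L) stopf("fewer than 2 segmentable images; cannot fit scaler")
    scaler <- fit_scaler(regions[ok])
  }
  rows <- lapply(seq_along(imgs), function(i) {
    fv <- if (ok[i]) compute_features(regions[[i]], grays[[i]], scaler)
          else fallback_features(grays[[i]])
    data.frame(id = manifest$id[i], label = manifest$label[i],
               MD = fv$MD, ED = fv$ED, WPD = fv$WPD, area = fv$area,
               perimeter = fv$perimeter,
               threshold = if (ok[i]) regions[[i]]$threshold else NA_integer_,
               fallback = as.integer(fv$fallback),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "scaler") <- scaler
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
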