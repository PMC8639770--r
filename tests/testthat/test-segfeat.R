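# Discriminant-analysis thresholding, focus-region selection and the
# MD/ED/WPD features.

test_that("otsu_threshold maximizes between-class variance with the tie rule", {
  h <- integer(256); h[11] <- 50L; h[201] <- 50L   # spikes at levels 10, 200
  expect_identical(otsu_threshold(h), 10L)

  # bimodal Gaussian mixture, modes 60 and 180 (mass large enough that the
  # inter-mode valley keeps nonzero counts)
  lv <- 0:255
  h2 <- round(5e4 * dnorm(lv, 60, 15) + 5e4 * dnorm(lv, 180, 15))
  t2 <- otsu_threshold(h2)
  expect_gte(t2, 100); expect_lte(t2, 140)
  expect_identical(t2, otsu_bruteforce(h2))

  h3 <- integer(256); h3[77] <- 1000L
  expect_error(otsu_threshold(h3), "degenerate image")
  expect_error(otsu_threshold(rep(1L, 100)), "256")
})

test_that("otsu_threshold agrees with the exhaustive scan on random histograms", {
  set.seed(31)
  for (i in 1:300) {
    h <- rpois(256, lambda = sample(c(0.5, 2, 10), 1))
    if (sum(h > 0) < 2) h[c(3, 200)] <- h[c(3, 200)] + 5L
    expect_identical(otsu_threshold(h), otsu_bruteforce(h))
  }
})

test_that("segment_focus picks the largest 8-connected component, deterministically", {
  # two saturated blobs on a gray background: areas ~500 and ~200
  img <- array(200, c(224, 224, 3))
  img[, , 2] <- 190  # slight tint so the image is not fully degenerate
  blob <- function(img, r0, c0, h, w) {
    img[r0:(r0 + h - 1), c0:(c0 + w - 1), 1] <- 60
    img[r0:(r0 + h - 1), c0:(c0 + w - 1), 2] <- 40
    img[r0:(r0 + h - 1), c0:(c0 + w - 1), 3] <- 120
    img
  }
  img <- blob(img, 30, 30, 25, 20)    # 500 px
  img <- blob(img, 150, 150, 20, 10)  # 200 px
  reg <- segment_focus(img)
  expect_identical(reg$area_px, 500L)
  expect_true(all(which(reg$mask, arr.ind = TRUE)[, 1] < 100))

  reg2 <- segment_focus(img)
  expect_identical(reg$mask, reg2$mask)

  expect_error(segment_focus(array(128, c(224, 224, 3))), "degenerate image")
})

test_that("8-connectivity joins diagonal pixels into one component", {
  lab <- focusCTA:::label_components(
    matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  expect_identical(length(unique(lab[lab > 0])), 1L)
  lab2 <- focusCTA:::label_components(diag(5) > 0)
  expect_identical(length(unique(lab2[lab2 > 0])), 1L)
})

test_that("segmentation recovers the generated cluster", {
  man <- study_manifest()
  pos_rows <- which(man$label == 1L)[1:3]
  imgs <- focusCTA:::manifest_images(man, pos_rows)
  for (im in imgs) {
    reg <- segment_focus(im)
    truth <- im$truth_mask
    expect_gte(sum(reg$mask & truth) / sum(truth), 0.8)
  }
})

test_that("perimeter estimator is accurate on squares and disks", {
  for (s in c(20, 50, 100)) {
    m <- matrix(FALSE, s + 20, s + 20)
    m[11:(10 + s), 11:(10 + s)] <- TRUE
    expect_lte(abs(region_perimeter(m) - 4 * s) / (4 * s), 0.05)
  }
  disk <- function(r) {
    n <- 2 * r + 21; cx <- (n + 1) / 2
    outer(1:n, 1:n, function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2)
  }
  for (r in c(15, 30, 60)) {
    m <- disk(r)
    efp <- pi * sqrt(4 * sum(m) / pi)
    expect_lt(abs(region_perimeter(m) - efp), 0.06 * efp)
  }
  # ED scale equivariance: doubling the radius quadruples AREA, doubles ED
  a1 <- sum(disk(30)); a2 <- sum(disk(60))
  expect_lt(abs(a2 / a1 - 4), 4 * 0.02)
  expect_lt(abs(sqrt(4 * a2 / pi) / sqrt(4 * a1 / pi) - 2), 2 * 0.02)
})

test_that("feature closed forms hold exactly", {
  gray <- matrix(137L, 20, 20)
  reg <- structure(list(mask = matrix(TRUE, 20, 20), area_px = 400L,
                        perimeter_px = 80, threshold = 5L),
                   class = "segmented_region")
  sc <- fit_scaler(c(100, 900))
  fv <- compute_features(reg, gray, sc)
  expect_identical(fv$MD, 137)                       # median of a constant
  expect_equal(fv$ED, sqrt(4 * 400 / pi))
  expect_equal(fv$EFP, pi * fv$ED)

  # area = 100 px^2: ED = sqrt(400/pi), EFP = pi * ED
  reg100 <- reg; reg100$area_px <- 100L
  reg100$mask <- matrix(FALSE, 20, 20); reg100$mask[1:10, 1:10] <- TRUE
  fv100 <- compute_features(reg100, gray, sc)
  expect_equal(fv100$ED, 11.283791671, tolerance = 1e-9)
  expect_equal(fv100$EFP, 35.449077018, tolerance = 1e-9)
  # AREA = AREA_min kills the weight regardless of the perimeter excess
  expect_identical(fv100$WPD, 0)

  # weight clamped to [0, 1] outside the training extremes
  reg_big <- reg; reg_big$area_px <- 5000L; reg_big$perimeter_px <- 500
  reg_big$mask <- matrix(TRUE, 20, 20)
  fv_big <- compute_features(reg_big, gray, sc)
  expect_equal(fv_big$WPD, 500 - pi * sqrt(4 * 5000 / pi))  # weight exactly 1

  # degenerate scaler: weight defined as 0, no error
  sc_dg <- suppressWarnings(fit_scaler(c(50, 50)))
  expect_identical(compute_features(reg, gray, sc_dg)$WPD, 0)
})

test_that("fit_scaler records the area extremes and validates its input", {
  sc <- fit_scaler(c(120, 400, 80))
  expect_identical(c(sc$area_min, sc$area_max), c(80, 400))
  expect_error(fit_scaler(100), "at least 2")
  expect_warning(fit_scaler(c(50, 50)), "degenerate")
  areas <- study_features()$train$area
  sc2 <- attr(study_features()$train, "scaler")
  expect_true(all(areas >= sc2$area_min & areas <= sc2$area_max))
})

test_that("batch extraction flags fallback rows instead of aborting", {
  man <- study_manifest()
  feats <- study_features()$train
  expect_identical(nrow(feats), 200L)
  expect_named(feats, c("id", "label", "MD", "ED", "WPD", "area",
                        "perimeter", "threshold", "fallback"))
  expect_true(all(feats$fallback %in% c(0L, 1L)))
  # fallback vector: background median, zero geometry
  g <- matrix(77L, 10, 10)
  fb <- focusCTA:::fallback_features(g)
  expect_identical(c(fb$MD, fb$ED, fb$WPD), c(77, 0, 0))
  expect_true(fb$fallback)
})
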