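# CNN harness: schedule, loss, augmentation, model construction, training
# contracts. Learning-quality checks live in the acceptance suite.

test_that("cosine annealing starts at lr_init, ends at lr_min, never increases", {
  lrs <- cosine_lr(0:49, 50, 1e-4)
  expect_identical(lrs[1], 1e-4)
  expect_identical(lrs[50], 0)
  expect_true(all(diff(lrs) <= 0))
  lrs2 <- cosine_lr(0:9, 10, 1e-3, lr_min = 1e-5)
  expect_identical(lrs2[1], 1e-3)
  expect_equal(lrs2[10], 1e-5)
  expect_identical(cosine_lr(0, 1, 5e-4), 5e-4)
})

test_that("batch loss equals independently recomputed binary cross-entropy", {
  set.seed(12)
  for (i in 1:20) {
    z <- rnorm(32, sd = 4); y <- rbinom(32, 1, 0.5)
    l <- focusCTA:::bce_with_logits(z, y)
    p <- 1 / (1 + exp(-z))
    expect_equal(l$loss, -mean(y * log(p) + (1 - y) * log(1 - p)),
                 tolerance = 1e-6)
    expect_equal(l$grad, (p - y) / 32, tolerance = 1e-9)
  }
})

test_that("augmentation is the identity at zero parameters and involutive under flips", {
  img <- render_image(sample_phenotype(1, "TPA-like", 2), c(224, 224), 4)$pixels
  img <- resize_bilinear(img, 64, 64)
  cfg <- train_config(rotation = 0, translation = 0, shear = 0, flip_prob = 0,
                      input_size = c(64, 64))
  expect_identical(augment(img, cfg), img)
  flip_par <- list(angle = 0, tx = 0, ty = 0, shear = 0, hflip = TRUE,
                   vflip = FALSE)
  once <- augment(img, cfg, params = flip_par)
  expect_false(identical(once, img))
  expect_identical(augment(once, cfg, params = flip_par), img)
  # deterministic under a fixed RNG state
  cfg2 <- train_config(input_size = c(64, 64), translation = 10)
  a <- withr::with_seed(5, augment(img, cfg2))
  b <- withr::with_seed(5, augment(img, cfg2))
  expect_identical(a, b)
  expect_identical(dim(a), dim(img))
})

test_that("augmentation parameters are uniform over the configured ranges", {
  cfg <- train_config()
  set.seed(21)
  draws <- replicate(1000, focusCTA:::draw_augment_params(cfg),
                     simplify = FALSE)
  ang <- vapply(draws, `[[`, numeric(1), "angle")
  expect_gt(ks.test(ang, "punif", -90, 90)$p.value, 0.01)
  tx <- vapply(draws, `[[`, numeric(1), "tx")
  expect_gt(ks.test(tx, "punif", -44, 44)$p.value, 0.01)
  sh <- vapply(draws, `[[`, numeric(1), "shear")
  expect_true(all(abs(sh) <= 15))
  flips <- mean(vapply(draws, `[[`, logical(1), "hflip"))
  expect_gt(flips, 0.4); expect_lt(flips, 0.6)
})

test_that("the residual network builds reproducibly with a single-logit head", {
  m1 <- build_model(seed = 4)
  m2 <- build_model(seed = 4)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$n_params, 11177025)   # standard 18-layer residual net
  expect_error(build_model(pretrained = TRUE), "scratch")

  x1 <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  l1 <- focusCTA:::resnet_forward(m1$params, m1$stats, x1)$logits
  expect_length(l1, 1)
  expect_true(is.finite(l1))
  xb <- array(rnorm(32 * 32 * 3 * 6), c(32, 32, 3, 6))
  lb <- focusCTA:::resnet_forward(m1$params, m1$stats, xb)$logits
  expect_length(lb, 6)
  expect_true(all(is.finite(lb)))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(33)
  x <- array(rnorm(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  y <- c(1, 0, 1, 0)
  mod <- build_model(seed = 3)
  p <- mod$params; s <- mod$stats
  fw <- focusCTA:::resnet_forward(p, s, x, training = TRUE, keep_cache = TRUE)
  gr <- focusCTA:::resnet_backward(
    p, fw$cache, focusCTA:::bce_with_logits(fw$logits, y)$grad)
  lossfun <- function(pp)
    focusCTA:::bce_with_logits(
      focusCTA:::resnet_forward(pp, s, x, training = TRUE)$logits, y)$loss
  eps <- 1e-5
  leaves <- list(
    list(function(pp) pp$layers[[1]][[1]]$w1,
         function(pp, v) { pp$layers[[1]][[1]]$w1 <- v; pp },
         gr$layers[[1]][[1]]$w1),
    list(function(pp) pp$layers[[2]][[1]]$wd,
         function(pp, v) { pp$layers[[2]][[1]]$wd <- v; pp },
         gr$layers[[2]][[1]]$wd),
    list(function(pp) pp$layers[[4]][[2]]$g1,
         function(pp, v) { pp$layers[[4]][[2]]$g1 <- v; pp },
         gr$layers[[4]][[2]]$g1),
    list(function(pp) pp$fc$w,
         function(pp, v) { pp$fc$w <- v; pp },
         gr$fc$w))
  for (lf in leaves) {
    for (i in c(1L, 5L)) {
      v <- lf[[1]](p); v[i] <- v[i] + eps
      lp <- lossfun(lf[[2]](p, v))
      v <- lf[[1]](p); v[i] <- v[i] - eps
      lm <- lossfun(lf[[2]](p, v))
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - lf[[3]][i]) / max(abs(num), 1e-6), 1e-4)
    }
  }
})

test_that("training honors the epoch contract and selects the best validation epoch", {
  man <- tiny_manifest()
  run <- cnn_train(man, tiny_cnn_config(seed = 1, epochs = 2))
  expect_identical(nrow(run$history), 2L)
  expect_true(run$selected_epoch %in% 1:2)
  expect_identical(run$selected_epoch,
                   which.max(run$history$val_acc))
  expect_named(run$history, c("epoch", "lr", "train_loss", "train_acc",
                              "val_loss", "val_acc"))
  expect_true(all(is.finite(as.matrix(run$history))))

  bad <- man
  bad$label[bad$split == "validation"] <- 1L
  expect_error(cnn_train(bad, tiny_cnn_config()), "both classes")
})

test_that("training is reproducible end to end", {
  man <- tiny_manifest()
  r1 <- cnn_train(man, tiny_cnn_config(seed = 3, epochs = 2))
  r2 <- cnn_train(man, tiny_cnn_config(seed = 3, epochs = 2))
  expect_identical(r1$history, r2$history)
  expect_identical(r1$checkpoint$params$fc$w, r2$checkpoint$params$fc$w)
})

test_that("prediction preserves order, handles duplicates and empty input", {
  man <- tiny_manifest()
  run <- cnn_train(man, tiny_cnn_config(seed = 2, epochs = 1))
  imgs <- focusCTA:::manifest_images(man, 1:4)
  p <- cnn_predict(run$checkpoint, imgs)
  expect_length(p, 4)
  expect_true(all(p > 0 & p < 1))
  pdup <- cnn_predict(run$checkpoint, imgs[c(1, 2, 1)])
  expect_identical(pdup[1], pdup[3])
  expect_identical(cnn_predict(run$checkpoint, list()), numeric(0))
  noise <- list(array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3)))
  pn <- cnn_predict(run$checkpoint, noise)
  expect_true(pn > 0 && pn < 1)
})

test_that("repeated trials summarize reproducible metrics", {
  man <- tiny_manifest()
  ts <- run_trials(man, tiny_cnn_config(epochs = 1), seeds = c(4, 4))
  expect_length(ts$runs, 2)
  expect_equal(ts$summary$sd, rep(0, 3))  # identical seeds, identical metrics
  recomputed <- summarize_trials(ts$reports)
  expect_equal(ts$summary, recomputed)
  expect_error(run_trials(man, tiny_cnn_config(), seeds = integer(0)))
})

test_that("transfer mode evaluates an external, id-disjoint manifest", {
  man <- tiny_manifest()
  expect_error(run_trials(man, tiny_cnn_config(epochs = 1), seeds = 1,
                          test_manifest = man), "shares ids")
  ext <- tiny_manifest(4, seed = 21)
  ext$id <- paste0("ext_", ext$id)
  ts <- run_trials(man, tiny_cnn_config(epochs = 1), seeds = 1,
                   test_manifest = ext)
  expect_identical(ts$reports[[1]]$n, 8L)
})
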