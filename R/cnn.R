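# CNN training/prediction harness: the full assay protocol (50 epochs,
# minibatch 32, Adam at 1e-4 with cosine annealing, geometric augmentation,
# checkpoint selection at maximal validation accuracy, repeated seeded
# trials). Scaled-down configurations differ only in the config values.

#' Training configuration for the CNN branch
#'
#' Defaults follow the full assay protocol: 50 epochs, minibatch 32, Adam
#' with initial learning rate 1e-4 decayed by cosine annealing to 0,
#' 224x224 inputs, augmentation by rotation in \[-90, 90\] degrees,
#' translation in \[-44, 44\] pixels, shear in \[-15, 15\] degrees and
#' horizontal/vertical flips with probability 0.5, training from scratch
#' (no pretraining).
#'
#' @param epochs,batch_size,lr_init,lr_min,input_size training hyperparameters.
#' @param rotation,translation,shear,flip_prob augmentation ranges (symmetric
#'   about 0) and flip probability.
#' @param seed master seed of one trial; initialization, shuffling and
#'   augmentation all derive from it.
#' @param pretrained must be `FALSE` (see [build_model()]).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L, lr_init = 1e-4,
                         lr_min = 0, input_size = c(224L, 224L),
                         rotation = 90, translation = 44, shear = 15,
                         flip_prob = 0.5, seed = 0L, pretrained = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 2, lr_init > 0, lr_min >= 0,
            all(input_size >= 8), rotation >= 0, translation >= 0,
            shear >= 0, flip_prob >= 0, flip_prob <= 1)
  if (isTRUE(pretrained))
    stopf("pretrained = TRUE is not supported; the protocol trains from scratch")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_min = lr_min,
                 input_size = as.integer(input_size),
                 rotation = rotation, translation = translation,
                 shear = shear, flip_prob = flip_prob,
                 seed = as.integer(seed), pretrained = FALSE),
            class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf(paste0("<train_config> %d epochs, batch %d, lr %g -> %g ",
                     "(cosine), input %dx%d\n  augmentation: rotation +/-%g deg, ",
                     "translation +/-%g px, shear +/-%g deg, flips p=%g; seed %d\n"),
              x$epochs, x$batch_size, x$lr_init, x$lr_min, x$input_size[1],
              x$input_size[2], x$rotation, x$translation, x$shear,
              x$flip_prob, x$seed))
  invisible(x)
}

#' Cosine-annealing learning rate
#'
#' `lr(0) = lr_init` and `lr(epochs - 1) = lr_min`, monotone nonincreasing
#' in between.
#'
#' @param epoch 0-based epoch index.
#' @param epochs total epochs (annealing period).
#' @param lr_init,lr_min schedule endpoints.
#' @export
cosine_lr <- function(epoch, epochs, lr_init, lr_min = 0) {
  stopifnot(epoch >= 0, epoch < epochs)
  if (epochs == 1L) return(lr_init + 0 * epoch)
  lr_min + (lr_init - lr_min) * (1 + cos(pi * epoch / (epochs - 1))) / 2
}

# Draw one set of augmentation parameters from the config's uniform ranges.
draw_augment_params <- function(config) {
  list(angle = stats::runif(1, -config$rotation, config$rotation),
       tx = stats::runif(1, -config$translation, config$translation),
       ty = stats::runif(1, -config$translation, config$translation),
       shear = stats::runif(1, -config$shear, config$shear),
       hflip = stats::runif(1) < config$flip_prob,
       vflip = stats::runif(1) < config$flip_prob)
}

#' Randomly augment an image at the network input size
#'
#' Applies random rotation, translation and shear (one affine warp with
#' bilinear resampling, constant-filled with the image's border-median
#' color) followed by independent horizontal/vertical flips. Parameters are
#' drawn from the current RNG state, so augmentation is deterministic under
#' `set.seed()`.
#'
#' @param pixels numeric `[h, w, 3]` array at the network input size.
#' @param config a [train_config()].
#' @param params optional fixed parameter list (as from the internal draw);
#'   when supplied, nothing is random.
#' @return augmented array of the same shape.
#' @export
augment <- function(pixels, config, params = NULL) {
  if (is.null(params)) params <- draw_augment_params(config)
  out <- warp_affine(pixels, angle = params$angle, shear = params$shear,
                     tx = params$tx, ty = params$ty)
  if (isTRUE(params$hflip)) out <- flip_horizontal(out)
  if (isTRUE(params$vflip)) out <- flip_vertical(out)
  out
}

# [0,255] -> mean 0.5 / sd 0.5 on the [0,1] scale
normalize_input <- function(pixels) (pixels / 255 - 0.5) / 0.5

# Stack a list of [h,w,3] arrays into [h,w,3,n]
stack_images <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(d[1], d[2], d[3], length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

# Resize every manifest image for the given split to the network input size.
prepare_split <- function(manifest, split, input_size) {
  rows <- which(manifest$split == split)
  if (length(rows) == 0L) stopf("split '%s' is empty", split)
  imgs <- manifest_images(manifest, rows)
  list(x = lapply(imgs, function(im)
         resize_bilinear(im$pixels, input_size[1], input_size[2])),
       y = manifest$label[rows], ids = manifest$id[rows])
}

#' Train the CNN on a split manifest
#'
#' Runs the configured number of epochs of minibatch Adam with cosine
#' annealing and per-batch augmentation, logging per-epoch training loss /
#' accuracy (running averages over the augmented minibatches) and
#' validation loss / accuracy (clean forward passes). The checkpoint is the
#' parameter state at the epoch of maximal validation accuracy (earliest on
#' ties). All randomness (initialization, shuffling, augmentation) derives
#' from `config$seed`.
#'
#' @param manifest a `focus_manifest` whose `split` column contains `train`
#'   and `validation` rows, each with both classes.
#' @param config a [train_config()].
#' @return object of class `train_run` with `config`, `history` (one row
#'   per epoch: `epoch, lr, train_loss, train_acc, val_loss, val_acc`),
#'   `selected_epoch` and `checkpoint`.
#' @export
cnn_train <- function(manifest, config = train_config()) {
  tr <- prepare_split(manifest, "train", config$input_size)
  va <- prepare_split(manifest, "validation", config$input_size)
  if (length(unique(tr$y)) < 2L || length(unique(va$y)) < 2L)
    stopf("train and validation splits must both contain both classes")
  model <- build_model(pretrained = FALSE, seed = config$seed)
  params <- model$params; stats <- model$stats
  m <- tree_map(function(a) a * 0, params)
  v <- tree_map(function(a) a * 0, params)
  hist_rows <- vector("list", config$epochs)
  best <- list(acc = -Inf, epoch = NA_integer_, params = NULL, stats = NULL)
  step <- 0L
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      lr <- cosine_lr(ep - 1L, config$epochs, config$lr_init, config$lr_min)
      ord <- sample(length(tr$y))
      nb <- ceiling(length(ord) / config$batch_size)
      ep_loss <- 0; ep_correct <- 0; ep_n <- 0
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1L) * config$batch_size + 1L):
                   min(b * config$batch_size, length(ord))]
        if (length(idx) < 2L) next  # batch norm needs >= 2 samples
        xb <- stack_images(lapply(tr$x[idx], function(px)
          normalize_input(augment(px, config))))
        yb <- tr$y[idx]
        fw <- resnet_forward(params, stats, xb, training = TRUE,
                             keep_cache = TRUE)
        stats <- fw$stats
        l <- bce_with_logits(fw$logits, yb)
        grads <- resnet_backward(params, fw$cache, l$grad)
        step <- step + 1L
        upd <- adam_step(params, grads, m, v, lr, step)
        params <- upd$params; m <- upd$m; v <- upd$v
        ep_loss <- ep_loss + l$loss * length(idx)
        ep_correct <- ep_correct + sum((fw$logits >= 0) == (yb == 1L))
        ep_n <- ep_n + length(idx)
      }
      vl <- eval_forward(params, stats, va$x, va$y, config)
      hist_rows[[ep]] <- data.frame(epoch = ep, lr = lr,
                                    train_loss = ep_loss / ep_n,
                                    train_acc = ep_correct / ep_n,
                                    val_loss = vl$loss, val_acc = vl$acc)
      if (vl$acc > best$acc) {
        # deep copy: the optimizer updates `params` in place
        best <- list(acc = vl$acc, epoch = ep, params = tree_copy(params),
                     stats = stats)
      }
    }
  })
  structure(list(config = config, history = do.call(rbind, hist_rows),
                 selected_epoch = best$epoch,
                 checkpoint = list(params = best$params, stats = best$stats,
                                   config = config)),
            class = "train_run")
}

# Clean (no augmentation) forward pass over a list of prepared images.
eval_forward <- function(params, stats, xs, ys, config, chunk = 64L) {
  logits <- numeric(length(xs))
  i <- 1L
  while (i <= length(xs)) {
    j <- min(i + chunk - 1L, length(xs))
    xb <- stack_images(lapply(xs[i:j], normalize_input))
    logits[i:j] <- resnet_forward(params, stats, xb, training = FALSE)$logits
    i <- j + 1L
  }
  l <- bce_with_logits(logits, ys)
  list(loss = l$loss, acc = mean((logits >= 0) == (ys == 1L)),
       probs = stats::plogis(logits))
}

#' @export
print.train_run <- function(x, ...) {
  cat(sprintf("<train_run> %d epochs, selected epoch %d (val acc %.3f)\n",
              nrow(x$history), x$selected_epoch,
              x$history$val_acc[x$selected_epoch]))
  invisible(x)
}

#' Predict focus probabilities with a trained checkpoint
#'
#' Images are resized to the network input size (no augmentation at
#' inference) and pushed through the selected checkpoint; outputs are
#' sigmoid probabilities, order-preserving with the input list.
#'
#' @param checkpoint the `checkpoint` element of a [cnn_train()] run (or a
#'   whole `train_run`).
#' @param images list of `focus_image` objects or `[h, w, 3]` arrays.
#' @return numeric vector of probabilities in `(0, 1)`.
#' @export
cnn_predict <- function(checkpoint, images) {
  if (inherits(checkpoint, "train_run")) checkpoint <- checkpoint$checkpoint
  if (length(images) == 0L) return(numeric(0))
  cfg <- checkpoint$config
  xs <- lapply(images, function(im) {
    px <- if (inherits(im, "focus_image")) im$pixels else im
    resize_bilinear(px, cfg$input_size[1], cfg$input_size[2])
  })
  eval_forward(checkpoint$params, checkpoint$stats, xs,
               rep(0L, length(xs)), cfg)$probs
}

#' Repeated seeded training trials
#'
#' Trains one CNN per seed, evaluates each selected checkpoint on the
#' `test` split (or an external test manifest for the transfer protocol)
#' and reports per-trial metrics plus their mean and sample standard
#' deviation.
#'
#' @param manifest a split `focus_manifest` with `train` and `validation`
#'   rows (and `test` rows unless `test_manifest` is given).
#' @param config a [train_config()]; its seed is replaced per trial.
#' @param seeds integer vector, one trial per seed.
#' @param test_manifest optional external test manifest (transfer mode);
#'   its ids must be disjoint from the training manifest.
#' @return object of class `trial_set` with `runs`, `reports` and `summary`.
#' @export
run_trials <- function(manifest, config = train_config(), seeds = 1:5,
                       test_manifest = NULL) {
  stopifnot(length(seeds) >= 1)
  if (!is.null(test_manifest)) {
    if (any(test_manifest$id %in% manifest$id))
      stopf("external test manifest shares ids with the training manifest")
    test_imgs <- manifest_images(test_manifest)
    test_y <- test_manifest$label
  } else {
    rows <- which(manifest$split == "test")
    if (length(rows) == 0L) stopf("no test split in manifest")
    test_imgs <- manifest_images(manifest, rows)
    test_y <- manifest$label[rows]
  }
  runs <- vector("list", length(seeds))
  reports <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    cfg <- config; cfg$seed <- as.integer(seeds[i])
    runs[[i]] <- tryCatch(cnn_train(manifest, cfg), error = function(e)
      stopf("trial with seed %d failed: %s", seeds[i], conditionMessage(e)))
    probs <- cnn_predict(runs[[i]]$checkpoint, test_imgs)
    reports[[i]] <- evaluate_scores(probs, test_y)
  }
  structure(list(runs = runs, reports = reports, seeds = as.integer(seeds),
                 summary = summarize_trials(reports)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials (seeds %s)\n", length(x$runs),
              paste(x$seeds, collapse = ", ")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a training history log as CSV
#' @param run a `train_run`.
#' @param path CSV path.
#' @export
write_history_csv <- function(run, path) {
  utils::write.csv(run$history, path, row.names = FALSE)
  invisible(path)
}
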