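# Shared fixtures, generated once per test run and cached in an environment.
# The "study" dataset is the maximal-contrast synthetic set used by the
# recovery checks: 150 positives + 150 negatives at 224x224, split
# 160 train / 40 validation / 100 test (stratified, seed 1).

.fixture_env <- new.env(parent = emptyenv())

study_manifest <- function() {
  if (is.null(.fixture_env$man)) {
    man <- generate_dataset(150, 150, rng_seed = 42, canvas = c(224L, 224L),
                            contrast = 1)
    man <- stratified_split(man, c(train = 160 / 300, validation = 40 / 300,
                                   test = 100 / 300), seed = 1)
    .fixture_env$man <- man
  }
  .fixture_env$man
}

manifest_subset <- function(man, rows) {
  out <- man[rows, , drop = FALSE]
  imgs <- attr(man, "images")
  if (!is.null(imgs)) attr(out, "images") <- imgs[rows]
  class(out) <- class(man)
  out
}

# MD/ED/WPD features of the study dataset: scaler fitted on the 200
# train+validation images, applied to the 100 test images.
study_features <- function() {
  if (is.null(.fixture_env$feats)) {
    man <- study_manifest()
    tr <- manifest_subset(man, which(man$split %in% c("train", "validation")))
    te <- manifest_subset(man, which(man$split == "test"))
    ftr <- extract_features(tr)
    fte <- extract_features(te, scaler = attr(ftr, "scaler"))
    .fixture_env$feats <- list(train = ftr, test = fte)
  }
  .fixture_env$feats
}

# The scaled-down CNN configuration: paper protocol with input 32x32
# (translation scaled to the same 20% of the input side), 10 epochs and a
# learning rate suited to the short schedule.
small_cnn_config <- function(seed = 1L, epochs = 10L) {
  train_config(epochs = epochs, batch_size = 32L, lr_init = 1e-3,
               input_size = c(32L, 32L), translation = 6, seed = seed)
}

# A tiny config for contract tests (fast, not meant to learn well).
tiny_cnn_config <- function(seed = 1L, epochs = 2L) {
  train_config(epochs = epochs, batch_size = 8L, lr_init = 1e-3,
               input_size = c(16L, 16L), translation = 3, seed = seed)
}

tiny_manifest <- function(n_per_class = 8L, seed = 7L) {
  key <- paste0("tiny_", n_per_class, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    man <- generate_dataset(n_per_class, n_per_class, rng_seed = seed,
                            canvas = c(224L, 224L))
    man <- stratified_split(man, c(train = 0.5, validation = 0.25,
                                   test = 0.25), seed = 1)
    .fixture_env[[key]] <- man
  }
  .fixture_env[[key]]
}

# Brute-force Mann-Whitney concordance (ties count 1/2): the AUC oracle.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive 256-threshold between-class-variance scan: the Otsu oracle.
otsu_bruteforce <- function(hist) {
  p <- hist / sum(hist); lv <- 0:255
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:254) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:(t + 1)] * lv[1:(t + 1)]) / w0
    mu1 <- sum(p[(t + 2):256] * lv[(t + 2):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-12) { best <- v; best_t <- t }
  }
  best_t
}

# Independent Dunnett-adjusted p-values via the multivariate t distribution
# (balanced or unbalanced many-to-one contrasts, two-sided).
dunnett_p_oracle <- function(counts, control) {
  concs <- sort(unique(counts$concentration))
  treated <- setdiff(concs, control)
  k <- length(treated)
  ns <- vapply(c(control, treated),
               function(g) sum(counts$concentration == g), numeric(1))
  means <- vapply(c(control, treated),
                  function(g) mean(counts$count[counts$concentration == g]),
                  numeric(1))
  ss <- sum(vapply(c(control, treated), function(g) {
    x <- counts$count[counts$concentration == g]; sum((x - mean(x))^2)
  }, numeric(1)))
  df <- sum(ns) - (k + 1)
  s2 <- ss / df
  tstat <- (means[-1] - means[1]) / sqrt(s2 * (1 / ns[-1] + 1 / ns[1]))
  lam <- sqrt(ns[-1] / (ns[-1] + ns[1]))
  R <- outer(lam, lam); diag(R) <- 1
  vapply(abs(tstat), function(ti)
    1 - mvtnorm::pmvt(lower = rep(-ti, k), upper = rep(ti, k), df = df,
                      corr = R)[1],
    numeric(1))
}
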