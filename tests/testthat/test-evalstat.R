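# Splitting, metrics, ROC/AUC, trial summaries, promotion call.

fake_manifest <- function(n_pos, n_neg) {
  structure(data.frame(id = sprintf("r%03d", seq_len(n_pos + n_neg)),
                       path = NA_character_,
                       label = c(rep(1L, n_pos), rep(0L, n_neg)),
                       chemical = "TPA-like", split = NA_character_,
                       stringsAsFactors = FALSE),
            class = c("focus_manifest", "data.frame"))
}

test_that("stratified splitting hits exact fractions on divisible classes", {
  man <- stratified_split(fake_manifest(100, 100), seed = 3)
  tab <- table(man$split, man$label)
  expect_identical(as.vector(tab[c("train", "validation", "test"), "1"]),
                   c(70L, 10L, 20L))
  expect_identical(as.vector(tab[c("train", "validation", "test"), "0"]),
                   c(70L, 10L, 20L))
  man2 <- stratified_split(fake_manifest(100, 100), seed = 3)
  expect_identical(man$split, man2$split)
})

test_that("stratification preserves the class ratio within one sample", {
  man <- stratified_split(fake_manifest(7, 3), seed = 1)
  tab <- table(factor(man$split, c("train", "validation", "test")), man$label)
  for (s in rownames(tab)) {
    n_s <- sum(tab[s, ])
    expect_lte(abs(tab[s, "1"] - n_s * 0.7), 1)
  }
  # property over random class sizes and seeds
  set.seed(5)
  for (i in 1:20) {
    np <- sample(5:60, 1); nn <- sample(5:60, 1)
    man <- stratified_split(fake_manifest(np, nn), seed = i)
    tab <- table(man$split, man$label)
    for (s in rownames(tab)) {
      n_s <- sum(tab[s, ])
      expect_lte(abs(tab[s, "1"] - n_s * np / (np + nn)), 1)
    }
    expect_identical(sum(tab), np + nn)
  }
  expect_error(stratified_split(fake_manifest(2, 50)), "at least")
  expect_error(stratified_split(fake_manifest(10, 10),
                                c(train = 0.5, test = 0.4)), "sum to 1")
})

test_that("confusion counts follow the score >= threshold convention", {
  expect_identical(confusion_at_threshold(c(0.9, 0.1), c(1, 0), 0.5),
                   c(TP = 1L, FP = 0L, FN = 0L, TN = 1L))
  cm <- confusion_at_threshold(rep(1, 10), rep(c(1, 0), 5), 0.5)
  expect_identical(cm[["FP"]], 5L); expect_identical(cm[["FN"]], 0L)
  cm0 <- confusion_at_threshold(runif(20), rbinom(20, 1, 0.5), 0)
  expect_identical(cm0[["TN"]] + cm0[["FN"]], 0L)  # everything positive at t=0
  expect_error(confusion_at_threshold(numeric(0), integer(0)), "nonempty")
})

test_that("ROC/AUC match Mann-Whitney concordance and anchor at the corners", {
  expect_identical(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_identical(roc_auc(rep(0.5, 10), rep(c(1, 0), 5))$auc, 0.5)
  expect_identical(roc_auc(c(0.8, 0.6, 0.4), c(1, 0, 1))$auc, 0.5)
  set.seed(77)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(c(1, 2, 8), 1))  # force some ties
    ra <- roc_auc(s, y)
    expect_equal(ra$auc, auc_bruteforce(s, y), tolerance = 1e-9)
    expect_identical(c(ra$roc$FPR[1], ra$roc$TPR[1]), c(0, 0))
    expect_identical(c(tail(ra$roc$FPR, 1), tail(ra$roc$TPR, 1)), c(1, 1))
    expect_true(all(diff(ra$roc$FPR) >= 0) && all(diff(ra$roc$TPR) >= 0))
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("random scores on a large balanced set give AUC near 1/2", {
  hits <- vapply(1:10, function(s) {
    set.seed(2000 + s)
    auc <- roc_auc(runif(2000), rep(c(0, 1), 1000))$auc
    auc >= 0.47 && auc <= 0.53
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("trial summaries report mean and sample SD per metric", {
  mk <- function(acc, rec, auc)
    structure(list(accuracy = acc, recall = rec, auc = auc),
              class = "eval_report")
  s3 <- summarize_trials(list(mk(0.9, 0.8, 0.95), mk(0.9, 0.8, 0.95),
                              mk(0.9, 0.8, 0.95)))
  expect_equal(s3$sd, rep(0, 3))
  s2 <- summarize_trials(list(mk(0.8, 0.9, 0.9), mk(0.9, 0.9, 1.0)))
  expect_equal(s2$mean[s2$metric == "auc"], 0.95)
  expect_equal(s2$sd[s2$metric == "auc"], 0.07071068, tolerance = 1e-6)
  s1 <- summarize_trials(list(mk(0.8, 0.9, 0.9)))
  expect_equal(s1$sd, rep(0, 3))
  expect_true(attr(s1, "n1_flag"))
})

test_that("evaluate_scores bundles a consistent report", {
  set.seed(4)
  y <- rbinom(50, 1, 0.6); s <- runif(50) + 0.3 * y
  r <- evaluate_scores(s, y)
  expect_identical(sum(r$confusion), 50L)
  expect_equal(r$accuracy, (r$confusion[["TP"]] + r$confusion[["TN"]]) / 50)
  expect_equal(r$recall,
               r$confusion[["TP"]] /
                 (r$confusion[["TP"]] + r$confusion[["FN"]]))
  f <- withr::local_tempfile(fileext = ".json")
  write_eval_report(r, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$auc, r$auc)
})

test_that("a clear two-consecutive elevation is called positive, matching the mvtnorm oracle", {
  counts <- data.frame(
    concentration = rep(c(0, 1, 2, 3), each = 6),
    count = c(0, 0, 0, 0, 0, 1,
              2, 3, 1, 4, 2, 2,
              2, 3, 1, 4, 2, 2,
              2, 3, 1, 4, 2, 2))
  call <- promotion_call(counts)
  expect_identical(call$decision, "positive")
  expect_true(all(call$p_values$dunnett_p < 0.05))
  oracle <- dunnett_p_oracle(counts, control = 0)
  # both routes integrate the multivariate t numerically; compare absolutely
  expect_lt(max(abs(call$p_values$dunnett_p - oracle)), 5e-4)
  expect_lt(call$anova_p, 0.05)
})

test_that("flat or single-peak plates are called negative", {
  flat <- data.frame(concentration = rep(c(0, 1, 2), each = 4),
                     count = rep(2, 12))
  call_flat <- promotion_call(flat)
  expect_identical(call_flat$decision, "negative")
  expect_true(call_flat$degenerate)

  set.seed(8)
  one_hit <- data.frame(
    concentration = rep(c(0, 5, 10, 20), each = 6),
    count = c(rpois(6, 1), rpois(6, 1), rpois(6, 1) + 8, rpois(6, 1)))
  call_one <- promotion_call(one_hit)
  expect_identical(sum(call_one$p_values$significant), 1L)
  expect_identical(call_one$decision, "negative")

  expect_error(promotion_call(data.frame(concentration = c(0, 1, 1),
                                         count = c(1, 2, 3))),
               "at least 2 wells")
})

test_that("the shipped synthetic TPA-like plate loads and is analyzable", {
  plate <- read_promotion_csv(system.file("extdata",
                                          "tpa_plate_synthetic.csv",
                                          package = "focusCTA"))
  expect_identical(nrow(plate), 24L)
  call <- promotion_call(plate)
  expect_true(call$decision %in% c("positive", "negative"))
  expect_equal(call$p_values$concentration, c(10, 20, 50))
})

test_that("Dunnett p-values decrease monotonically with the effect size", {
  base <- c(-1, -0.5, 0, 0.5, 1)   # zero-mean, fixed spread
  pvals <- vapply(c(0, 1, 2, 3, 4), function(shift) {
    counts <- data.frame(
      concentration = rep(c(0, 1, 2), each = 5),
      count = c(base + 3, base + 3 + shift, base + 3))
    promotion_call(counts)$p_values$dunnett_p[1]
  }, numeric(1))
  expect_true(all(diff(pvals) < 0))
})
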