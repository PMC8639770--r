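# Evaluation machinery: stratified splitting, confusion matrix, accuracy,
# recall, ROC/AUC, multi-trial summaries, and the assay-level tumour-
# promotion decision rule.

#' Stratified train/validation/test split
#'
#' Assigns each manifest record to a split by per-class shuffling (with
#' `seed`) followed by proportional allocation with largest-remainder
#' rounding, so every split's class ratio is preserved within one sample.
#' The main-protocol fractions are 70/10/20; the transfer protocol uses
#' 90/10 with an external test set.
#'
#' @param manifest a `focus_manifest`.
#' @param fractions named fractions over the splits, in `(0, 1]`, summing
#'   to 1 (default `c(train = .7, validation = .1, test = .2)`).
#' @param seed integer seed.
#' @param stratified allocate per class (default) or over the pooled set.
#' @return the manifest with its `split` column filled in.
#' @export
stratified_split <- function(manifest,
                             fractions = c(train = 0.7, validation = 0.1,
                                           test = 0.2),
                             seed = 0L, stratified = TRUE) {
  if (is.null(names(fractions)) || any(fractions <= 0) || any(fractions > 1))
    stopf("fractions must be named values in (0, 1]")
  if (abs(sum(fractions) - 1) > 1e-9) stopf("fractions must sum to 1")
  n_splits <- length(fractions)
  groups <- if (stratified) split(seq_len(nrow(manifest)), manifest$label)
            else list(seq_len(nrow(manifest)))
  if (any(vapply(groups, length, integer(1)) < n_splits))
    stopf("each class needs at least %d samples for %d splits",
          n_splits, n_splits)
  assign_split <- manifest$split
  seeds <- derive_seeds(seed, length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    idx <- with_seed(seeds[g], sample(idx))
    counts <- largest_remainder(length(idx) * fractions)
    assign_split[idx] <- rep(names(fractions), counts)
  }
  manifest$split <- assign_split
  manifest
}

# Largest-remainder (Hamilton) apportionment of fractional targets to
# integers summing to round(sum(x)); ties go to the earlier entry.
largest_remainder <- function(x) {
  fl <- floor(x + 1e-12)
  rem <- x - fl
  extra <- round(sum(x)) - sum(fl)
  if (extra > 0) {
    ord <- order(-rem, seq_along(x))
    fl[ord[seq_len(extra)]] <- fl[ord[seq_len(extra)]] + 1
  }
  as.integer(fl)
}

#' Confusion matrix at a probability threshold
#'
#' A score `>= threshold` predicts the positive class.
#'
#' @param scores numeric vector of probabilities.
#' @param labels 0/1 vector of the same length, nonempty.
#' @param threshold decision threshold (default 0.5).
#' @return named integer vector `c(TP, FP, FN, TN)`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L || length(scores) != length(labels))
    stopf("scores and labels must be nonempty and equal-length")
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  c(TP = sum(pred == 1L & labels == 1L), FP = sum(pred == 1L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L), TN = sum(pred == 0L & labels == 0L))
}

#' ROC curve and AUC
#'
#' Sweeps all distinct score values as thresholds to build the ROC polygon
#' and integrates it by the trapezoidal rule, which makes the AUC equal to
#' the Mann-Whitney concordance probability with ties counted 1/2 (0.5 for a
#' completely random model, 1.0 for the ideal).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 vector; both classes must be present.
#' @return list with `roc` (data.frame `threshold, FPR, TPR`, anchored at
#'   (0,0) and (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stopf("both classes required for ROC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- cumsum(rep(1, length(s)))[!duplicated(s, fromLast = TRUE)]
  tp <- cumsum(y)[last]; fp <- (last - cumsum(y)[last])
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  thr <- c(Inf, unique(s))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thr, FPR = fpr, TPR = tpr), auc = auc)
}

#' Evaluate classifier scores against labels
#'
#' Bundles the confusion matrix at `threshold`, accuracy, recall
#' (sensitivity on the positive, transformed-focus class), the ROC polygon
#' and the AUC into one report.
#'
#' @inheritParams confusion_at_threshold
#' @return object of class `eval_report`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  cm <- confusion_at_threshold(scores, labels, threshold)
  ra <- roc_auc(scores, labels)
  n <- length(labels)
  structure(list(confusion = cm, accuracy = (cm[["TP"]] + cm[["TN"]]) / n,
                 recall = cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]),
                 roc = ra$roc, auc = ra$auc, n = n, threshold = threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  accuracy=%.3f  recall=%.3f  AUC=%.3f\n",
              x$n, x$accuracy, x$recall, x$auc))
  cat(sprintf("  confusion (t=%.2f): TP=%d FP=%d FN=%d TN=%d\n", x$threshold,
              x$confusion[["TP"]], x$confusion[["FP"]], x$confusion[["FN"]],
              x$confusion[["TN"]]))
  invisible(x)
}

#' Serialize an evaluation report
#' @param report an `eval_report`.
#' @param path JSON path; with `roc_csv`, the ROC points are also written
#'   as CSV.
#' @param roc_csv optional CSV path for the ROC points.
#' @export
write_eval_report <- function(report, path, roc_csv = NULL) {
  jsonlite::write_json(list(confusion = as.list(report$confusion),
                            accuracy = report$accuracy, recall = report$recall,
                            auc = report$auc, n = report$n,
                            threshold = report$threshold,
                            roc = report$roc),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc_csv)) utils::write.csv(report$roc, roc_csv, row.names = FALSE)
  invisible(path)
}

#' Mean and standard deviation of metrics over repeated trials
#'
#' @param reports list of [evaluate_scores()] reports (one per trial).
#' @return data.frame with one row per metric (`accuracy`, `recall`, `auc`)
#'   and columns `mean`, `sd`, `n`; the sample SD (n-1) is reported, 0 with
#'   an `n1_flag` when only one trial is supplied.
#' @export
summarize_trials <- function(reports) {
  if (length(reports) < 1L) stopf("need at least one report")
  metrics <- c("accuracy", "recall", "auc")
  vals <- sapply(metrics, function(m)
    vapply(reports, function(r) r[[m]], numeric(1)))
  vals <- matrix(vals, nrow = length(reports),
                 dimnames = list(NULL, metrics))
  out <- data.frame(metric = metrics,
                    mean = colMeans(vals),
                    sd = if (length(reports) == 1L) 0
                         else apply(vals, 2, stats::sd),
                    n = length(reports), row.names = NULL)
  attr(out, "n1_flag") <- length(reports) == 1L
  out
}

# ---- promotion-activity decision rule -------------------------------------

#' Assay-level tumour-promotion call
#'
#' One-way ANOVA over per-well focus counts by concentration, followed by
#' two-sided Dunnett many-to-one comparisons of each treated concentration
#' against the control. A chemical is called a promoter when the focus
#' frequency is significantly increased (Dunnett p < `alpha`) at two
#' consecutive members of the tested concentration ladder.
#'
#' @param counts data.frame with columns `concentration` and `count`
#'   (nonnegative integers, one row per well), at least 2 wells per
#'   concentration.
#' @param control the control concentration (default: the smallest).
#' @param alpha significance level (default 0.05).
#' @param gatekeep if `TRUE`, the Dunnett comparisons only count when the
#'   ANOVA F-test itself is significant at `alpha`.
#' @param seed seed for the multivariate-t integration behind the Dunnett
#'   adjustment (makes the randomized quadrature reproducible).
#' @return object of class `promotion_call`: the decision, the ANOVA
#'   p-value, per-concentration Dunnett p-values and the flagged
#'   (significant) concentrations.
#' @export
promotion_call <- function(counts, control = NULL, alpha = 0.05,
                           gatekeep = FALSE, seed = 1L) {
  stopifnot(is.data.frame(counts),
            all(c("concentration", "count") %in% names(counts)))
  if (any(counts$count < 0)) stopf("counts must be nonnegative")
  concs <- sort(unique(counts$concentration))
  if (is.null(control)) control <- min(concs)
  if (!control %in% concs) stopf("control concentration not present")
  tab <- table(counts$concentration)
  if (any(tab < 2L)) stopf("each concentration needs at least 2 wells")
  treated <- setdiff(concs, control)
  lev <- c(control, treated)
  dat <- data.frame(
    count = counts$count,
    group = factor(counts$concentration, levels = lev))
  fit <- stats::aov(count ~ group, data = dat)
  ss <- summary(fit)[[1]]
  anova_p <- ss[["Pr(>F)"]][1]
  # exact ties within every group leave the test statistics undefined
  degenerate <- all(tapply(dat$count, dat$group,
                           function(x) stats::var(x) == 0))
  if (degenerate) {
    # exact ties within every group: p-values are untestable; the decision
    # falls back to strict mean elevation over control (flagged degenerate)
    means <- tapply(dat$count, dat$group, mean)
    pvals <- rep(NA_real_, length(treated))
    sig <- unname(means[as.character(treated)] > means[as.character(control)])
    consec <- length(treated) >= 2 && any(sig[-1] & sig[-length(sig)])
    decision <- if (consec) "positive" else "negative"
    flagged <- treated[sig]
  } else {
    dn <- with_seed(seed, summary(multcomp::glht(
      fit, linfct = multcomp::mcp(group = "Dunnett"),
      alternative = "two.sided")))
    pvals <- as.numeric(dn$test$pvalues)
    sig <- pvals < alpha
    if (gatekeep && !(is.finite(anova_p) && anova_p < alpha)) sig[] <- FALSE
    # two consecutive members of the concentration ladder, both significant
    consec <- length(treated) >= 2 && any(sig[-1] & sig[-length(sig)])
    decision <- if (consec) "positive" else "negative"
    flagged <- treated[sig]
  }
  structure(list(decision = decision, anova_p = anova_p,
                 p_values = data.frame(concentration = treated,
                                       dunnett_p = pvals,
                                       significant = as.logical(sig)),
                 flagged = flagged, control = control, alpha = alpha,
                 gatekeep = gatekeep, degenerate = degenerate),
            class = "promotion_call")
}

#' @export
print.promotion_call <- function(x, ...) {
  cat(sprintf("Promotion call: %s (alpha = %g, control = %g%s)\n",
              toupper(x$decision), x$alpha, x$control,
              if (x$degenerate) ", degenerate: zero within-group variance"
              else ""))
  cat(sprintf("  ANOVA p = %s\n", format(x$anova_p, digits = 4)))
  print(x$p_values, row.names = FALSE)
  invisible(x)
}

#' Read per-well focus counts
#'
#' CSV with columns `concentration,well,count` (the `well` column is
#' optional and ignored by the statistics). A synthetic example plate with
#' realistic TPA-like per-concentration focus-count moments ships with the
#' package:
#' `system.file("extdata", "tpa_plate_synthetic.csv", package = "focusCTA")`.
#' @param path CSV path.
#' @return data.frame suitable for [promotion_call()].
#' @export
read_promotion_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("concentration", "count") %in% names(d)))
    stopf("promotion CSV needs columns concentration,count")
  d
}
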