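# Classical branch, stage 2: logistic regression over (MD, ED, WPD).

#' Fit the logistic-regression focus classifier
#'
#' Maximum-likelihood logistic regression on standardized MD/ED/WPD features
#' by Newton-Raphson (IRLS), with a tiny ridge penalty on the slopes
#' (`ridge`, default 1e-6) guarding against separation-induced divergence.
#' The fit is deterministic given its inputs; `seed` is recorded in the
#' training metadata.
#'
#' @param features numeric matrix or data.frame with columns `MD`, `ED`,
#'   `WPD` (extra columns such as those from [extract_features()] are
#'   ignored).
#' @param labels 0/1 vector, both classes present, >= 2 samples per class.
#' @param seed integer, recorded in `training_meta`.
#' @param ridge ridge penalty on the standardized slopes.
#' @return object of class `focus_logistic`.
#' @export
fit_logistic <- function(features, labels, seed = 0L, ridge = 1e-6) {
  X <- as.matrix(as.data.frame(features)[, c("MD", "ED", "WPD")])
  storage.mode(X) <- "double"
  y <- as.integer(labels)
  if (nrow(X) != length(y)) stopf("features and labels differ in length")
  if (!all(y %in% c(0L, 1L))) stopf("labels must be 0/1")
  if (min(table(factor(y, levels = 0:1))) < 2L)
    stopf("need at least 2 samples per class")
  if (!all(is.finite(X))) stopf("features must be finite")
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1   # constant feature carries no information
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  Zi <- cbind(`(Intercept)` = 1, Z)
  beta <- rep(0, ncol(Zi))
  pen <- diag(c(0, rep(ridge, ncol(Z))))   # intercept unpenalized
  for (it in seq_len(100L)) {
    eta <- drop(Zi %*% beta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(Zi, y - p)) - pen %*% beta
    if (max(abs(g)) < 1e-10) break
    Wd <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Zi * Wd, Zi) + pen
    beta <- beta + solve(H, g)
  }
  structure(list(coefficients = drop(beta), feature_means = mu,
                 feature_sds = sds, ridge = ridge,
                 training_meta = list(seed = as.integer(seed), n = length(y),
                                      class_counts = c(negative = sum(y == 0L),
                                                       positive = sum(y == 1L)))),
            class = "focus_logistic")
}

#' @export
coef.focus_logistic <- function(object, ...) object$coefficients

#' @export
print.focus_logistic <- function(x, ...) {
  cat("Logistic focus classifier (standardized MD/ED/WPD)\n")
  print(round(x$coefficients, 4))
  m <- x$training_meta
  cat(sprintf("n = %d (neg %d / pos %d), seed = %d\n", m$n,
              m$class_counts[["negative"]], m$class_counts[["positive"]],
              m$seed))
  invisible(x)
}

#' @export
summary.focus_logistic <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Predicted probability of the positive (transformed-focus) class
#'
#' @param object a fitted `focus_logistic`.
#' @param newdata matrix/data.frame with columns `MD`, `ED`, `WPD`, or a
#'   single `feature_vector`.
#' @param type `"response"` (probability) or `"link"` (linear score).
#' @param ... unused.
#' @return numeric vector in `(0, 1)` (for `"response"`).
#' @export
predict.focus_logistic <- function(object, newdata,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_vector"))
    newdata <- data.frame(MD = newdata$MD, ED = newdata$ED, WPD = newdata$WPD)
  X <- as.matrix(as.data.frame(newdata)[, c("MD", "ED", "WPD")])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stopf("non-finite feature")
  Z <- sweep(sweep(X, 2, object$feature_means), 2, object$feature_sds, "/")
  eta <- drop(cbind(1, Z) %*% object$coefficients)
  if (type == "link") return(eta)
  # keep probabilities in the open interval even when the score saturates
  eps <- .Machine$double.eps
  pmin(pmax(stats::plogis(eta), eps), 1 - eps)
}

#' @rdname predict.focus_logistic
#' @param model a fitted `focus_logistic`.
#' @param features features of one or more candidates.
#' @export
predict_proba <- function(model, features) {
  predict(model, features, type = "response")
}

#' Serialize / restore a logistic model as JSON
#' @param model a `focus_logistic`.
#' @param path JSON file path.
#' @export
write_logistic_json <- function(model, path) {
  jsonlite::write_json(list(coefficients = as.list(model$coefficients),
                            feature_means = as.list(model$feature_means),
                            feature_sds = as.list(model$feature_sds),
                            ridge = model$ridge,
                            training_meta = model$training_meta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_logistic_json
#' @export
read_logistic_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(j$coefficients),
                 feature_means = unlist(j$feature_means),
                 feature_sds = unlist(j$feature_sds),
                 ridge = j$ridge,
                 training_meta = j$training_meta),
            class = "focus_logistic")
}
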