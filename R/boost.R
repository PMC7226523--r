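#' Gradient-boosted Cox proportional-hazards ensemble
#'
#' Stagewise minimization of the negative Cox partial log-likelihood
#' (Breslow form) with depth-limited regression trees fitted to the current
#' gradient; leaf values are Newton steps shrunk by the learning rate.
#' Predictions are relative log-risk scores (higher = worse). The fit is
#' deterministic: no row or column subsampling is used.
#'
#' @param features data frame / tibble of numeric features (samples x p).
#' @param times survival times.
#' @param events 0/1 event indicators; at least 2 events required.
#' @param hyperparams list with `n_stages`, `learning_rate`, `max_depth`,
#'   `min_leaf` (missing entries take the defaults 100 / 0.1 / 2 / 5).
#' @param seed kept for interface stability; the fit does not consume
#'   randomness.
#' @return Object of class `radprog_boost` with the tree ensemble, the
#'   training-loss path and the training feature names.
#' @export
fit_boosted_cox <- function(features, times, events, hyperparams = list(), seed = 1L) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("fit_boosted_cox: features must be finite")
  if (sum(events) < 2) stop("fit_boosted_cox: need at least 2 events")
  hp <- utils::modifyList(list(n_stages = 100L, learning_rate = 0.1,
                               max_depth = 2L, min_leaf = 5L), hyperparams)
  fit <- cpp_boost_fit(X, as.numeric(times), as.integer(events), "cox",
                       as.integer(hp$n_stages), hp$learning_rate,
                       as.integer(hp$max_depth), as.integer(hp$min_leaf))
  structure(list(loss = "cox", f0 = fit$f0, trees = fit$trees,
                 train_loss = fit$train_loss, fitted = fit$fitted,
                 feature_names = colnames(X), hyperparams = hp),
            class = "radprog_boost")
}

#' Gradient-boosted logistic ensemble for recurrence
#'
#' Same boosting machinery as [fit_boosted_cox()] with the binomial deviance:
#' the ensemble starts at the log-odds of the prevalence (so a 0-stage model
#' scores every sample at the prevalence) and returns probabilities.
#'
#' @param features data frame / tibble of numeric features.
#' @param labels 0/1 outcome labels (both classes required).
#' @inheritParams fit_boosted_cox
#' @return Object of class `radprog_boost` (`loss = "logistic"`).
#' @export
fit_boosted_classifier <- function(features, labels, hyperparams = list(), seed = 1L) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("fit_boosted_classifier: features must be finite")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("fit_boosted_classifier: both classes required")
  hp <- utils::modifyList(list(n_stages = 100L, learning_rate = 0.1,
                               max_depth = 2L, min_leaf = 5L), hyperparams)
  fit <- cpp_boost_fit(X, numeric(length(labels)), labels, "logistic",
                       as.integer(hp$n_stages), hp$learning_rate,
                       as.integer(hp$max_depth), as.integer(hp$min_leaf))
  structure(list(loss = "logistic", f0 = fit$f0, trees = fit$trees,
                 train_loss = fit$train_loss, fitted = fit$fitted,
                 feature_names = colnames(X), hyperparams = hp),
            class = "radprog_boost")
}

#' @export
print.radprog_boost <- function(x, ...) {
  cat("<radprog_boost> ", x$loss, " loss, ", length(x$trees), " stages (lr ",
      x$hyperparams$learning_rate, ", depth ", x$hyperparams$max_depth, "), ",
      length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

#' Predict from a boosted ensemble
#'
#' @param object a `radprog_boost` model.
#' @param newdata data frame with (at least) the training feature columns.
#' @param type `"link"` for the additive score (log-risk / log-odds);
#'   `"response"` applies the logistic link for classification models.
#' @param n_stages optionally truncate the ensemble to its first stages.
#' @param ... unused.
#' @export
predict.radprog_boost <- function(object, newdata, type = c("link", "response"),
                                  n_stages = NULL, ...) {
  type <- match.arg(type)
  X <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  ns <- if (is.null(n_stages)) length(object$trees) else n_stages
  f <- cpp_boost_predict(object$trees, object$f0, X, as.integer(ns))
  if (type == "response" && object$loss == "logistic") plogis(f) else f
}

#' Serialize a boosted ensemble to JSON
#'
#' Writes trees (node tables), loss, intercept, hyperparameters and feature
#' names; [read_boost_json()] restores a functionally identical model.
#'
#' @param model a `radprog_boost`.
#' @param file path to write.
#' @export
write_boost_json <- function(model, file) {
  payload <- list(loss = model$loss, f0 = model$f0,
                  hyperparams = model$hyperparams,
                  feature_names = model$feature_names,
                  trees = lapply(model$trees, function(tm) {
                    colnames(tm) <- c("feature", "threshold", "left", "right", "value")
                    as.data.frame(tm)
                  }))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_boost_json
#' @export
read_boost_json <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  trees <- lapply(seq_len(if (is.data.frame(p$trees)) 1 else length(p$trees)),
                  function(i) {
                    df <- if (is.data.frame(p$trees)) p$trees else p$trees[[i]]
                    as.matrix(df)
                  })
  structure(list(loss = p$loss, f0 = p$f0, trees = trees,
                 train_loss = NULL, fitted = NULL,
                 feature_names = p$feature_names,
                 hyperparams = as.list(p$hyperparams)),
            class = "radprog_boost")
}
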