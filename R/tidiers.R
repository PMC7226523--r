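# broom-style tidiers and ggplot2 autoplot methods for the result objects

#' @export
tidy.radprog_boost <- function(x, ...) {
  tibble::tibble(stage = seq_along(x$trees),
                 train_loss = as.numeric(x$train_loss),
                 n_nodes = vapply(x$trees, nrow, integer(1)))
}

#' @export
glance.radprog_boost <- function(x, ...) {
  tibble::tibble(loss = x$loss, n_stages = length(x$trees),
                 learning_rate = x$hyperparams$learning_rate,
                 max_depth = x$hyperparams$max_depth,
                 n_features = length(x$feature_names),
                 final_train_loss = utils::tail(as.numeric(x$train_loss), 1))
}

#' @export
tidy.selection_report <- function(x, ...) x$frequencies

#' @export
glance.selection_report <- function(x, ...) {
  tibble::tibble(endpoint = x$endpoint,
                 n_resamples = x$config$n_resamples,
                 signature_size = length(x$final_signature),
                 max_frequency = max(x$frequencies$frequency))
}

#' @export
tidy.resampling_result <- function(x, ...) x$results

#' @export
glance.resampling_result <- function(x, ...) {
  mets <- intersect(c("ci", "auc", "auprc"), names(x$results))
  out <- tibble::tibble(endpoint = x$endpoint, mode = x$mode,
                        n_metrics = nrow(x$results),
                        n_excluded = nrow(x$excluded))
  for (m in mets) {
    out[[paste0("mean_", m)]] <- mean(x$results[[m]])
    out[[paste0("sd_", m)]] <- sd(x$results[[m]])
  }
  out
}

#' @export
tidy.model_comparison <- function(x, ...) x$summary

#' @export
tidy.km_strata <- function(x, ...) x$curves

#' @export
glance.km_strata <- function(x, ...) {
  tibble::tibble(logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p,
                 cut = x$cut)
}

#' @export
tidy.cluster_assignment <- function(x, ...) x$clusters

#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the result objects:
#' metric distributions for `resampling_result` and `model_comparison`
#' (box/violin, one panel per metric), selection frequencies for
#' `selection_report`, and survivor step curves for `km_strata` or averaged
#' curves from [average_km()].
#'
#' @param object the result object.
#' @param top_n for selection reports, how many features to show.
#' @param ... unused.
#' @name radprog-autoplot
NULL

#' @rdname radprog-autoplot
#' @export
autoplot.resampling_result <- function(object, ...) {
  mets <- intersect(c("ci", "auc", "auprc"), names(object$results))
  long <- tidyr::pivot_longer(object$results, dplyr::all_of(mets),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
    ggplot2::labs(y = "outer test metric", x = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname radprog-autoplot
#' @export
autoplot.model_comparison <- function(object, ...) {
  ggplot2::ggplot(object$raw,
                  ggplot2::aes(x = .data$model, y = .data$value,
                               fill = .data$model)) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4, fill = "white") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "outer test metric") +
    ggplot2::theme_minimal()
}

#' @rdname radprog-autoplot
#' @export
autoplot.selection_report <- function(object, top_n = 20, ...) {
  tab <- head(object$frequencies, top_n)
  tab$feature <- factor(tab$feature, levels = rev(tab$feature))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$frequency, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "selection frequency", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname radprog-autoplot
#' @export
autoplot.km_strata <- function(object, ...) {
  plot_km_curves(object$curves) +
    ggplot2::labs(subtitle = sprintf("log-rank p = %.3g", object$logrank_p))
}

#' @rdname radprog-autoplot
#' @param curves a tibble with `group`, `time`, `surv` (e.g. from
#'   [average_km()]).
#' @export
plot_km_curves <- function(curves, ...) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$surv,
                                       color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  color = "risk group") +
    ggplot2::theme_minimal()
}

#' Forest-plot data and plot for a univariate screen
#'
#' Shows each feature's univariate concordance index with its normal 95%
#' interval (CI of the fitted single-covariate linear predictor).
#'
#' @param screen a survival [univariate_screen()] result (needs `statistic`,
#'   `beta`, `se` columns).
#' @param features optional subset of features to display.
#' @return A ggplot object.
#' @export
plot_forest <- function(screen, features = NULL) {
  stopifnot(all(c("statistic", "beta", "se") %in% names(screen)))
  tab <- if (is.null(features)) screen else screen[screen$feature %in% features, ]
  # delta-method style half-width on the concordance scale via p: use the
  # Wald interval of beta mapped through the observed CI displacement
  half <- abs(tab$statistic - 0.5) * (1.96 * tab$se / pmax(abs(tab$beta), 1e-9))
  half <- pmin(half, 0.49)
  tab$lo <- pmax(tab$statistic - half, 0)
  tab$hi <- pmin(tab$statistic + half, 1)
  tab$feature <- factor(tab$feature, levels = rev(tab$feature))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$statistic, y = .data$feature)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "univariate concordance index", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
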