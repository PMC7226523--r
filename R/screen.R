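#' Univariate Cox screen of one feature
#'
#' Single-covariate Cox proportional-hazards fit (Efron tie handling, Newton
#' iteration) with the Wald p-value and the univariate concordance index of
#' the fitted linear predictor.
#'
#' @param x numeric feature values.
#' @param times,events survival outcome (>= 2 events).
#' @return One-row tibble: `statistic` (univariate CI), `beta`, `se`,
#'   `raw_p`, `flagged` (TRUE for constant/degenerate features).
#' @export
univariate_cox <- function(x, times, events) {
  if (sum(events) < 2) stop("univariate_cox: need at least 2 events")
  if (length(unique(x)) < 2) {
    return(tibble::tibble(statistic = NA_real_, beta = NA_real_, se = NA_real_,
                          raw_p = NA_real_, flagged = TRUE))
  }
  xs <- as.numeric(scale(x))   # stabilizes Newton steps; p and CI are invariant
  fit <- cpp_coxph1(xs, as.numeric(times), as.integer(events))
  ci <- suppressWarnings(concordance_index(fit$beta * xs, times, events))
  p <- if (is.na(fit$se)) NA_real_ else 2 * pnorm(-abs(fit$beta / fit$se))
  tibble::tibble(statistic = as.numeric(ci), beta = fit$beta, se = fit$se,
                 raw_p = p, flagged = !fit$converged && is.na(p))
}

#' Univariate one-way ANOVA screen of one feature
#'
#' One-way F test of the feature across outcome classes.
#'
#' @param x numeric feature values.
#' @param labels class labels (e.g. 0/1 recurrence).
#' @return One-row tibble: `statistic` (F), `raw_p`, `flagged`.
#' @export
univariate_anova <- function(x, labels) {
  g <- as.factor(labels)
  if (nlevels(g) < 2) stop("univariate_anova: need at least 2 classes")
  if (length(unique(x)) < 2) {
    return(tibble::tibble(statistic = NA_real_, raw_p = NA_real_, flagged = TRUE))
  }
  n <- length(x); k <- nlevels(g)
  gm <- tapply(x, g, mean); gn <- tabulate(g)
  ssb <- sum(gn * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  df1 <- k - 1; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  tibble::tibble(statistic = f, raw_p = pf(f, df1, df2, lower.tail = FALSE),
                 flagged = !is.finite(f))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegates to [stats::p.adjust()]).
#'
#' @param raw_p numeric vector of p-values (NA allowed).
#' @return Adjusted p-values, order-preserving and elementwise `>= raw_p`.
#' @export
fdr_adjust <- function(raw_p) p.adjust(raw_p, method = "BH")

#' Screen every feature of a table univariately
#'
#' Runs [univariate_cox()] (survival endpoint) or [univariate_anova()]
#' (class endpoint) over all feature columns and attaches BH-FDR adjusted
#' p-values. Constant features are flagged and excluded from ranking but
#' kept in the output. The ANOVA branch is computed by vectorized group
#' sums for speed.
#'
#' @param features tibble/data frame of numeric feature columns (a
#'   `patient_id` column, if present, is ignored).
#' @param times,events survival outcome (survival endpoint).
#' @param labels class labels (class endpoint); give either `times`+`events`
#'   or `labels`.
#' @return Tibble: `feature`, `statistic`, `raw_p`, `fdr_p`, `flagged`
#'   (plus `beta`, `se` for the Cox branch), sorted as the input columns.
#' @export
univariate_screen <- function(features, times = NULL, events = NULL, labels = NULL) {
  X <- drop_id(features)
  if (!is.null(labels)) {
    res <- anova_screen_matrix(as.matrix(X), labels)
  } else {
    stopifnot(!is.null(times), !is.null(events))
    res <- cox_screen_matrix(as.matrix(X), times, events)
  }
  res <- tibble::add_column(res, feature = names(X), .before = 1)
  res$fdr_p <- fdr_adjust(res$raw_p)
  res
}

# vectorized-loop Cox screen; same model as univariate_cox() without
# per-feature data-frame overhead (matters at 841 features x 1000 resamples)
cox_screen_matrix <- function(X, times, events) {
  p <- ncol(X); n <- nrow(X)
  times <- as.numeric(times); events <- as.integer(events)
  stat <- beta <- se <- raw_p <- rep(NA_real_, p)
  flagged <- logical(p)
  for (j in seq_len(p)) {
    x <- X[, j]
    s <- sd(x)
    if (!is.finite(s) || s == 0) { flagged[j] <- TRUE; next }
    xs <- (x - mean(x)) / s
    fit <- cpp_coxph1(xs, times, events)
    cc <- cpp_concordance(fit$beta * xs, times, events)
    stat[j] <- cc$ci
    beta[j] <- fit$beta; se[j] <- fit$se
    raw_p[j] <- if (is.na(fit$se)) NA_real_ else 2 * pnorm(-abs(fit$beta / fit$se))
    flagged[j] <- !fit$converged && is.na(raw_p[j])
  }
  tibble::tibble(statistic = stat, beta = beta, se = se, raw_p = raw_p,
                 flagged = flagged)
}

anova_screen_matrix <- function(X, labels) {
  g <- as.factor(labels)
  k <- nlevels(g); n <- nrow(X)
  gn <- tabulate(g)
  tot_mean <- colMeans(X)
  ssb <- 0
  gm <- rowsum(X, g) / gn
  ssb <- colSums(gn * (sweep(gm, 2, tot_mean))^2)
  sst <- colSums(sweep(X, 2, tot_mean)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  const <- apply(X, 2, function(col) length(unique(col)) < 2)
  f[const | !is.finite(f)] <- NA_real_
  tibble::tibble(statistic = unname(f),
                 raw_p = pf(unname(f), df1, df2, lower.tail = FALSE),
                 flagged = unname(const | !is.finite(f)))
}

drop_id <- function(features) {
  df <- as.data.frame(features, check.names = FALSE)
  df[, setdiff(names(df), "patient_id"), drop = FALSE]
}
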