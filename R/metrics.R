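#' Harrell concordance index
#'
#' Fraction of comparable patient pairs whose predicted risk ordering matches
#' the observed survival ordering. A pair is comparable when the survival
#' times differ and the earlier time is an observed event; tied-time pairs
#' (including two simultaneous events) are not comparable. Tied risks in a
#' comparable pair count 0.5.
#'
#' @param risks numeric risk scores (higher = worse prognosis).
#' @param times survival times.
#' @param events 0/1 event indicators (1 = event observed).
#' @return Concordance index in `[0, 1]`, with attributes `comparable`,
#'   `concordant`, `discordant`, `tied_risk`. `NA` (flagged) when no pair is
#'   comparable.
#' @export
concordance_index <- function(risks, times, events) {
  stopifnot(length(risks) == length(times), length(times) == length(events))
  r <- cpp_concordance(as.numeric(risks), as.numeric(times), as.integer(events))
  out <- r$ci
  attributes(out) <- r[c("comparable", "concordant", "discordant", "tied_risk")]
  if (r$comparable == 0) warning("concordance_index: no comparable pairs")
  out
}

#' Area under the ROC curve
#'
#' Mann-Whitney pairwise probability that a positive outscores a negative;
#' score ties count 0.5 (computed via midranks).
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`; `NA` with a warning if only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("roc_auc: only one class present")
    return(NA_real_)
  }
  rk <- rank(scores)     # midranks handle ties as 0.5
  (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step interpolation: walking thresholds from the highest score down, the
#' area is `sum over recall increments of precision at that threshold`
#' (no linear interpolation between PR points, which would be optimistic at
#' small n). Tied scores enter as one threshold block. A constant scorer
#' yields AUPRC equal to the prevalence.
#'
#' @inheritParams roc_auc
#' @return AUPRC in `[0, 1]`; `NA` with a warning if only one class present.
#' @export
pr_auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1)
  if (npos == 0 || npos == length(labels)) {
    warning("pr_auprc: only one class present")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))          # threshold blocks of tied scores
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' ROC and precision-recall coordinates
#'
#' @inheritParams roc_auc
#' @return Tibble with one row per threshold block: `threshold`, `tpr`,
#'   `fpr`, `precision`, `recall`.
#' @export
roc_pr_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  npos <- sum(y); nneg <- sum(1 - y)
  tibble::tibble(threshold = s[last],
                 tpr = tp[last] / max(npos, 1),
                 fpr = fp[last] / max(nneg, 1),
                 precision = tp[last] / (tp[last] + fp[last]),
                 recall = tp[last] / max(npos, 1))
}

#' Median-risk stratification with Kaplan-Meier curves and log-rank test
#'
#' Splits patients at the median risk score, estimates the Kaplan-Meier
#' survivor function per group and tests the difference with the two-group
#' log-rank test (1 df, via the survival package).
#'
#' @inheritParams concordance_index
#' @return Object of class `km_strata`: tibble of curves (`group`, `time`,
#'   `surv`, `n_risk`, `n_event`), `logrank_chisq`, `logrank_p`, `cut`.
#' @export
stratify_and_km <- function(risks, times, events) {
  cut <- median(risks)
  group <- factor(ifelse(risks > cut, "high", "low"), levels = c("low", "high"))
  if (any(table(group) == 0)) stop("stratify_and_km: a risk group is empty")
  df <- data.frame(time = times, event = as.integer(events), group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata_names <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  curves <- tibble::tibble(group = strata_names, time = fit$time,
                           surv = fit$surv, n_risk = fit$n.risk,
                           n_event = fit$n.event)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chisq <- sd_$chisq
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  structure(list(curves = curves, logrank_chisq = chisq, logrank_p = p,
                 cut = cut), class = "km_strata")
}

#' @export
print.km_strata <- function(x, ...) {
  cat("<km_strata> median-risk split at ", signif(x$cut, 4),
      "; log-rank chisq = ", signif(x$logrank_chisq, 4),
      " (p = ", signif(x$logrank_p, 3), ")\n", sep = "")
  invisible(x)
}

# survivor step function evaluated at a grid (right-continuous, S(0) = 1)
km_eval <- function(time, surv, grid) {
  if (length(time) == 0) return(rep(1, length(grid)))
  f <- stats::stepfun(time, c(1, surv), right = FALSE)
  f(grid)
}

#' Average Kaplan-Meier curves over test sets
#'
#' Evaluates each curve on a common time grid and averages pointwise, as used
#' to summarize risk-group survival across outer-loop test sets.
#'
#' @param km_list list of `km_strata` objects (or of their `curves` tibbles).
#' @param grid common time grid; defaults to 100 points spanning all curves.
#' @return Tibble with `group`, `time`, `surv` (the pointwise mean).
#' @export
average_km <- function(km_list, grid = NULL) {
  curves <- lapply(km_list, function(k) if (inherits(k, "km_strata")) k$curves else k)
  all_t <- unlist(lapply(curves, function(cv) cv$time))
  if (is.null(grid)) grid <- seq(0, max(all_t), length.out = 100)
  groups <- sort(unique(unlist(lapply(curves, function(cv) cv$group))))
  out <- list()
  for (g in groups) {
    mat <- vapply(curves, function(cv) {
      sub <- cv[cv$group == g, ]
      km_eval(sub$time, sub$surv, grid)
    }, numeric(length(grid)))
    out[[g]] <- tibble::tibble(group = g, time = grid,
                               surv = rowMeans(as.matrix(mat)))
  }
  dplyr::bind_rows(out)
}
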