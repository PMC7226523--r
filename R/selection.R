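#' Configuration of the resampled 3-step feature selection
#'
#' @param n_resamples number of subsampling repeats (1000 replicates the
#'   reference analysis; tests use fewer).
#' @param subsample_fraction fraction of samples drawn without replacement
#'   per repeat (2/3).
#' @param fdr_cutoff univariate screen keeps features with BH-FDR adjusted
#'   p below this value (a loose cutoff; downstream steps do the real
#'   winnowing). If nothing passes, the `fallback_top_n` smallest raw p
#'   survive.
#' @param screen_top_n cap on the number of screened features carried into
#'   pruning (kept by raw p).
#' @param fallback_top_n number of features kept when the FDR cutoff admits
#'   none.
#' @param cor_threshold Pearson threshold for [correlation_prune()].
#' @param max_size largest subset explored by [sffs()].
#' @param cv_folds folds of the internal cross-validated objective.
#' @param hyperparams boosted-model hyperparameters for the objective refits
#'   (small on purpose: the objective ranks subsets, it does not tune).
#' @param refit_reps repeated-CV replicates used to size the final signature.
#' @param screen_stats attach full-data univariate screen statistics to the
#'   frequency table (informative, but skippable when selection runs inside
#'   resampling loops).
#' @param seed RNG seed.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(n_resamples = 1000, subsample_fraction = 2 / 3,
                             fdr_cutoff = 0.25, screen_top_n = 30,
                             fallback_top_n = 10, cor_threshold = 0.8,
                             max_size = 8, cv_folds = 3,
                             hyperparams = list(n_stages = 25, learning_rate = 0.2,
                                                max_depth = 2, min_leaf = 5),
                             refit_reps = 5, screen_stats = TRUE, seed = 1L) {
  structure(as.list(environment()), class = "selection_config")
}

# stratified k-fold assignment (uses the current RNG stream)
make_folds <- function(strata, k) {
  n <- length(strata)
  fold <- integer(n)
  for (s in unique(strata)) {
    ix <- sample(which(strata == s))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

# cross-validated objective for a feature subset (uses current RNG for folds)
cv_objective <- function(X, outcome, subset, folds = 3, hyperparams = list()) {
  survival_mode <- is.null(outcome$labels)
  strata <- if (survival_mode) outcome$event else outcome$labels
  fold <- make_folds(strata, folds)
  vals <- c()
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, subset, drop = FALSE]; Xte <- X[te, subset, drop = FALSE]
    val <- tryCatch({
      if (survival_mode) {
        m <- fit_boosted_cox(Xtr, outcome$time[tr], outcome$event[tr], hyperparams)
        suppressWarnings(as.numeric(concordance_index(
          predict(m, Xte), outcome$time[te], outcome$event[te])))
      } else {
        m <- fit_boosted_classifier(Xtr, outcome$labels[tr], hyperparams)
        suppressWarnings(roc_auc(predict(m, Xte), outcome$labels[te]))
      }
    }, error = function(e) NA_real_)
    vals <- c(vals, val)
  }
  mean(vals, na.rm = TRUE)
}

#' Resampled 3-step feature selection
#'
#' Repeats, on random two-thirds subsamples drawn without replacement: a
#' univariate screen (Cox model for the survival endpoint, one-way ANOVA for
#' the class endpoint) with BH-FDR cutoff, recursive correlation pruning,
#' and SFFS with a cross-validated boosted-model objective. Selection
#' frequencies are aggregated over repeats, and the final signature is the
#' top-frequency feature set whose size is chosen by a one-standard-error
#' rule on a repeated-CV refit objective.
#'
#' @param features feature table (tibble; `patient_id` column ignored).
#' @param times,events survival outcome (survival endpoint), or
#' @param labels class labels (recurrence endpoint).
#' @param config a [selection_config()].
#' @return Object of class `selection_report`: `frequencies` tibble
#'   (feature, frequency, screen statistics on the full data), `subsets`
#'   (per-resample selections), `final_signature`, `refit` tibble (size,
#'   mean, se), and the config.
#' @export
resampled_selection <- function(features, times = NULL, events = NULL,
                                labels = NULL, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  X <- drop_id(features)
  Xm <- as.data.frame(X, check.names = FALSE)
  n <- nrow(Xm)
  survival_mode <- is.null(labels)
  outcome <- list(time = times, event = events, labels = labels)
  set.seed(config$seed)

  m_sub <- max(2L, floor(config$subsample_fraction * n))
  subsets <- vector("list", config$n_resamples)
  for (b in seq_len(config$n_resamples)) {
    for (try in 1:20) {
      ix <- sample.int(n, m_sub)
      ok <- if (survival_mode) sum(events[ix]) >= 2 else length(unique(labels[ix])) >= 2
      if (ok) break
    }
    subsets[[b]] <- select_once(Xm[ix, , drop = FALSE],
                                list(time = times[ix], event = events[ix],
                                     labels = labels[ix]),
                                survival_mode, config)
  }

  freq <- table(factor(unlist(subsets), levels = names(Xm)))
  freq_tbl <- tibble::tibble(feature = names(Xm),
                             frequency = as.numeric(freq) / config$n_resamples)
  if (isTRUE(config$screen_stats)) {
    scr <- if (survival_mode) univariate_screen(Xm, times = times, events = events)
           else univariate_screen(Xm, labels = labels)
    freq_tbl <- dplyr::left_join(freq_tbl, scr, by = "feature")
  }
  freq_tbl <- dplyr::arrange(freq_tbl, dplyr::desc(.data$frequency), .data$feature)

  ranked <- freq_tbl$feature[freq_tbl$frequency > 0]
  kmax <- min(length(ranked), config$max_size)
  refit <- NULL
  final <- head(ranked, 1)
  if (kmax >= 1) {
    means <- ses <- numeric(kmax)
    for (k in seq_len(kmax)) {
      vals <- vapply(seq_len(config$refit_reps), function(r)
        cv_objective(Xm, outcome, head(ranked, k), config$cv_folds,
                     config$hyperparams), numeric(1))
      means[k] <- mean(vals, na.rm = TRUE)
      ses[k] <- sd(vals, na.rm = TRUE) / sqrt(sum(is.finite(vals)))
    }
    refit <- tibble::tibble(size = seq_len(kmax), mean = means, se = ses)
    kbest <- which.max(means)
    k1se <- which(means >= means[kbest] - ses[kbest])[1]  # smallest within 1 SE
    final <- head(ranked, k1se)
  }
  structure(list(frequencies = freq_tbl, subsets = subsets,
                 final_signature = final, refit = refit,
                 endpoint = if (survival_mode) "survival" else "recurrence",
                 config = config),
            class = "selection_report")
}

# one subsample: screen -> prune -> SFFS
select_once <- function(Xs, out_s, survival_mode, config) {
  keep <- vapply(Xs, function(col) length(unique(col)) > 1, logical(1))
  Xs <- Xs[, keep, drop = FALSE]
  if (!ncol(Xs)) return(character(0))
  scr <- if (survival_mode)
    univariate_screen(Xs, times = out_s$time, events = out_s$event)
  else univariate_screen(Xs, labels = out_s$labels)
  scr <- scr[!scr$flagged & is.finite(scr$raw_p), ]
  pass <- scr[scr$fdr_p < config$fdr_cutoff, ]
  if (nrow(pass) == 0)
    pass <- scr[order(scr$raw_p), ][seq_len(min(config$fallback_top_n, nrow(scr))), ]
  pass <- pass[order(pass$raw_p), ]
  pass <- head(pass, config$screen_top_n)
  cand <- pass$feature
  if (length(cand) > 1) {
    scores <- setNames(-log(pmax(pass$raw_p, 1e-300)), pass$feature)
    cand <- correlation_prune(Xs[, cand, drop = FALSE], scores,
                              config$cor_threshold)
  }
  if (length(cand) <= 1) return(cand)
  obj <- function(s) cv_objective(Xs, out_s, s, config$cv_folds, config$hyperparams)
  as.character(sffs(cand, obj, config$max_size))
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> ", x$endpoint, " endpoint, ",
      x$config$n_resamples, " resamples\n", sep = "")
  cat("  final signature (", length(x$final_signature), "): ",
      paste(x$final_signature, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export a selection report
#'
#' Writes the frequency table (feature, class, frequency, univariate
#' statistic, FDR p) as CSV and the whole report (including per-resample
#' subsets) as JSON.
#'
#' @param report a `selection_report`.
#' @param csv,json output paths (either may be `NULL`).
#' @export
write_selection_report <- function(report, csv = NULL, json = NULL) {
  tab <- report$frequencies
  if (!is.null(csv)) write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(endpoint = report$endpoint,
                              final_signature = report$final_signature,
                              frequencies = tab,
                              subsets = report$subsets,
                              config = unclass(report$config)),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
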