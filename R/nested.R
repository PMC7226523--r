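#' Nested resampling specification
#'
#' Outer repeated k-fold cross-validation for performance estimation,
#' wrapping an inner repeated k-fold loop for hyperparameter tuning. The
#' reference configuration is 500 x 3-fold outer / 100 x 3-fold inner
#' (collecting 1500 outer test metrics); scaled-down loops are used for
#' desk-scale runs.
#'
#' @param outer_reps,outer_folds outer loop (defaults 500 x 3).
#' @param inner_reps,inner_folds inner tuning loop (defaults 100 x 3).
#' @param seed integer seed; fixes the fold stream, so models evaluated with
#'   the same spec and outcomes share outer folds (paired comparison).
#' @return list of class `resampling_spec`.
#' @export
resampling_spec <- function(outer_reps = 500, outer_folds = 3,
                            inner_reps = 100, inner_folds = 3, seed = 1L) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, outer_reps >= 1, inner_reps >= 1)
  structure(list(outer_reps = as.integer(outer_reps),
                 outer_folds = as.integer(outer_folds),
                 inner_reps = as.integer(inner_reps),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)), class = "resampling_spec")
}

#' Default hyperparameter grid for the boosted models
#'
#' A small grid over ensemble size and learning rate at tree depth 2.
#'
#' @return Tibble with columns `n_stages`, `learning_rate`, `max_depth`,
#'   `min_leaf`.
#' @export
default_grid <- function() {
  tidyr::expand_grid(n_stages = c(25L, 75L), learning_rate = c(0.1, 0.3),
                     max_depth = 2L, min_leaf = 5L)
}

#' Nested cross-validated evaluation of a prognostic model
#'
#' For every outer repetition the cohort is split into stratified folds
#' (stratified on the event/label so no fold is event-free at small n). Per
#' outer fold, hyperparameters are tuned by the inner repeated CV on the
#' outer-training data, the boosted model is refit on the full outer-train
#' and scored on the untouched outer-test patients. Feature selection can be
#' run inside each outer-train (`selection`, leak-free default for new
#' analyses) or a fixed `feature_set` can be supplied — e.g. a signature
#' selected on the whole dataset, which replicates the original analysis'
#' acknowledged leak and is labelled as such in the result.
#'
#' @param features feature table (tibble; `patient_id` ignored). May also
#'   contain clinical columns; `feature_set`/`selection` decide what enters
#'   the model.
#' @param times,events survival outcome (concordance-index endpoint), or
#' @param labels binary labels (AUC/AUPRC endpoint).
#' @param feature_set character vector of model features (fixed-signature
#'   mode).
#' @param selection optional [selection_config()]: run selection inside each
#'   outer-train on all feature columns; `selection_candidates` can restrict
#'   the candidate columns (e.g. exclude clinical covariates from selection
#'   but force them into the model via `always_include`).
#' @param always_include columns appended to every model (e.g. the five
#'   clinical covariates of the combined model).
#' @param spec a [resampling_spec()].
#' @param grid hyperparameter grid (tibble); a single row skips tuning.
#' @param selection_candidates optional candidate columns for `selection`.
#' @param verbose print one line per outer rep.
#' @return Object of class `resampling_result`: `results` (tibble: rep,
#'   fold, n_test, metric column(s), chosen hyperparameters, signature
#'   size), `predictions` (per-test-set risk scores), `excluded` (flagged
#'   folds), the spec and mode labels.
#' @export
nested_evaluate <- function(features, times = NULL, events = NULL, labels = NULL,
                            feature_set = NULL, selection = NULL,
                            always_include = character(0),
                            spec = resampling_spec(), grid = default_grid(),
                            selection_candidates = NULL, verbose = FALSE) {
  X <- drop_id(features)
  survival_mode <- is.null(labels)
  strata <- if (survival_mode) as.integer(events) else as.integer(labels)
  n <- nrow(X)
  if (is.null(feature_set) && is.null(selection))
    stop("nested_evaluate: give either feature_set or selection")
  if (!is.null(feature_set) && !all(feature_set %in% names(X)))
    stop("nested_evaluate: feature_set columns missing from features")

  set.seed(spec$seed)
  folds <- replicate(spec$outer_reps, make_folds(strata, spec$outer_folds))
  work_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                  spec$outer_reps * spec$outer_folds),
                       spec$outer_reps, spec$outer_folds)

  res_rows <- list(); pred_rows <- list(); excl_rows <- list()
  for (rep_i in seq_len(spec$outer_reps)) {
    fold <- folds[, rep_i]
    for (f in seq_len(spec$outer_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      set.seed(work_seeds[rep_i, f])
      out <- evaluate_one_fold(X, tr, te, survival_mode,
                               list(time = times, event = events, labels = labels),
                               feature_set, selection, always_include,
                               selection_candidates, spec, grid)
      if (is.null(out$metric) || all(is.na(unlist(out$metric)))) {
        excl_rows[[length(excl_rows) + 1L]] <-
          tibble::tibble(rep = rep_i, fold = f, reason = out$reason)
        next
      }
      res_rows[[length(res_rows) + 1L]] <- tibble::tibble(
        rep = rep_i, fold = f, n_test = length(te),
        !!!out$metric,
        n_stages = out$hp$n_stages, learning_rate = out$hp$learning_rate,
        max_depth = out$hp$max_depth, signature_size = length(out$features))
      pred_rows[[length(pred_rows) + 1L]] <- tibble::tibble(
        rep = rep_i, fold = f, index = te, risk = out$risk)
    }
    if (verbose) message("outer rep ", rep_i, "/", spec$outer_reps)
  }
  structure(list(results = dplyr::bind_rows(res_rows),
                 predictions = dplyr::bind_rows(pred_rows),
                 excluded = dplyr::bind_rows(excl_rows),
                 endpoint = if (survival_mode) "survival" else "recurrence",
                 mode = if (is.null(selection)) "fixed_signature" else "selection_in_loop",
                 spec = spec),
            class = "resampling_result")
}

evaluate_one_fold <- function(X, tr, te, survival_mode, out_all,
                              feature_set, selection, always_include,
                              selection_candidates, spec, grid) {
  out_tr <- list(time = out_all$time[tr], event = out_all$event[tr],
                 labels = out_all$labels[tr])
  ok <- if (survival_mode) sum(out_tr$event) >= 2 else length(unique(out_tr$labels)) >= 2
  if (!ok) return(list(metric = NULL, reason = "degenerate training outcome"))

  feats <- feature_set
  if (!is.null(selection)) {
    cand_cols <- if (is.null(selection_candidates)) names(X) else selection_candidates
    cand_cols <- setdiff(cand_cols, always_include)
    sel <- if (survival_mode)
      resampled_selection(X[tr, cand_cols, drop = FALSE],
                          times = out_tr$time, events = out_tr$event,
                          config = selection)
    else
      resampled_selection(X[tr, cand_cols, drop = FALSE],
                          labels = out_tr$labels, config = selection)
    feats <- sel$final_signature
  }
  feats <- unique(c(feats, always_include))

  # leak-free per-fold normalization (monotone per feature; kept for parity
  # with the selection stage, harmless for tree models)
  ntr <- normalize_features(X[tr, feats, drop = FALSE])
  nte <- apply_normalization(X[te, feats, drop = FALSE], ntr)

  hp <- as.list(grid[1, ])
  if (nrow(grid) > 1) {
    scores <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      hp_g <- as.list(grid[g, ])
      vals <- c()
      for (ir in seq_len(spec$inner_reps)) {
        strat_tr <- if (survival_mode) out_tr$event else out_tr$labels
        ifold <- make_folds(strat_tr, spec$inner_folds)
        for (k in seq_len(spec$inner_folds)) {
          itr <- ifold != k; ite <- !itr
          v <- tryCatch({
            if (survival_mode) {
              m <- fit_boosted_cox(ntr[itr, , drop = FALSE], out_tr$time[itr],
                                   out_tr$event[itr], hp_g)
              suppressWarnings(as.numeric(concordance_index(
                predict(m, ntr[ite, , drop = FALSE]),
                out_tr$time[ite], out_tr$event[ite])))
            } else {
              m <- fit_boosted_classifier(ntr[itr, , drop = FALSE],
                                          out_tr$labels[itr], hp_g)
              suppressWarnings(roc_auc(predict(m, ntr[ite, , drop = FALSE]),
                                       out_tr$labels[ite]))
            }
          }, error = function(e) NA_real_)
          vals <- c(vals, v)
        }
      }
      scores[g] <- mean(vals, na.rm = TRUE)
    }
    scores[!is.finite(scores)] <- -Inf
    hp <- as.list(grid[which.max(scores), ])
  }

  if (survival_mode) {
    m <- fit_boosted_cox(ntr, out_tr$time, out_tr$event, hp)
    risk <- predict(m, nte)
    ci <- suppressWarnings(concordance_index(risk, out_all$time[te], out_all$event[te]))
    if (is.na(ci)) return(list(metric = NULL, reason = "no comparable test pairs"))
    list(metric = list(ci = as.numeric(ci)), risk = risk, hp = hp, features = feats)
  } else {
    m <- fit_boosted_classifier(ntr, out_tr$labels, hp)
    risk <- predict(m, nte, type = "response")
    auc <- suppressWarnings(roc_auc(risk, out_all$labels[te]))
    auprc <- suppressWarnings(pr_auprc(risk, out_all$labels[te]))
    if (is.na(auc)) return(list(metric = NULL, reason = "single-class test fold"))
    list(metric = list(auc = auc, auprc = auprc), risk = risk, hp = hp,
         features = feats)
  }
}

#' @export
print.resampling_result <- function(x, ...) {
  cat("<resampling_result> ", x$endpoint, ", ", x$mode, ": ",
      nrow(x$results), " test metrics collected (", nrow(x$excluded),
      " folds excluded)\n", sep = "")
  mets <- intersect(c("ci", "auc", "auprc"), names(x$results))
  for (m in mets)
    cat("  mean ", m, " = ", signif(mean(x$results[[m]]), 4),
        " (sd ", signif(sd(x$results[[m]]), 3), ")\n", sep = "")
  invisible(x)
}

#' Patient-level risk averaging and Kaplan-Meier stratification
#'
#' Averages each patient's predicted risk over all outer test sets that
#' contained the patient, splits at the median average risk and returns the
#' Kaplan-Meier comparison of the two groups.
#'
#' @param result a survival `resampling_result` from [nested_evaluate()].
#' @param times,events the cohort outcome used in the evaluation.
#' @return A `km_strata` object (see [stratify_and_km()]).
#' @export
risk_stratification <- function(result, times, events) {
  stopifnot(inherits(result, "resampling_result"))
  pr <- dplyr::summarise(dplyr::group_by(result$predictions, .data$index),
                         risk = mean(.data$risk), .groups = "drop")
  pr <- dplyr::arrange(pr, .data$index)
  stratify_and_km(pr$risk, times[pr$index], events[pr$index])
}

#' Compare clinical, radiomic and combined models
#'
#' Summarizes (mean, dispersion) the outer-loop metric distributions of the
#' three models evaluated under a shared resampling spec.
#'
#' @param clinical,radiomic,combined `resampling_result` objects; any may be
#'   omitted, and further named models can be added via `...`.
#' @param ... further named `resampling_result`s.
#' @return Object of class `model_comparison`: `summary` tibble (model,
#'   metric, mean, sd, n), `raw` long tibble of all metric values.
#' @export
compare_models <- function(clinical = NULL, radiomic = NULL, combined = NULL, ...) {
  models <- c(list(clinical = clinical, radiomic = radiomic, combined = combined),
              list(...))
  models <- models[!vapply(models, is.null, logical(1))]
  if (!length(models)) stop("compare_models: no models given")
  raw <- dplyr::bind_rows(lapply(names(models), function(nm) {
    r <- models[[nm]]
    stopifnot(inherits(r, "resampling_result"))
    mets <- intersect(c("ci", "auc", "auprc"), names(r$results))
    tidyr::pivot_longer(r$results[, c("rep", "fold", mets)], dplyr::all_of(mets),
                        names_to = "metric", values_to = "value") |>
      dplyr::mutate(model = nm, .before = 1)
  }))
  summ <- dplyr::summarise(dplyr::group_by(raw, .data$model, .data$metric),
                           mean = mean(.data$value), sd = sd(.data$value),
                           n = dplyr::n(), .groups = "drop")
  summ$model <- factor(summ$model, levels = names(models))
  structure(list(summary = dplyr::arrange(summ, .data$model, .data$metric),
                 raw = raw), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' The five clinical covariates as numeric model inputs
#'
#' @param clinical the `clinical` tibble of a cohort (integer-coded gender,
#'   T stage, N stage, site, resection).
#' @return Tibble with the five covariate columns, numeric.
#' @export
clinical_features <- function(clinical) {
  cols <- c("gender", "t_stage", "n_stage", "site", "resection")
  stopifnot(all(cols %in% names(clinical)))
  dplyr::mutate(clinical[, cols], dplyr::across(dplyr::everything(), as.numeric))
}
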