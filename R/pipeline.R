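#' Pipeline run configuration
#'
#' Bundles every stage's settings and seeds for an end-to-end run
#' (simulate -> extract -> select -> evaluate -> cluster -> report). The
#' configuration round-trips to YAML via [write_run_config()] /
#' [read_run_config()].
#'
#' @param cohort a [cohort_spec()].
#' @param extraction an [extraction_config()].
#' @param selection a [selection_config()].
#' @param resampling a [resampling_spec()].
#' @param grid hyperparameter grid (data frame).
#' @param k_clusters patient clusters for the heatmap stage.
#' @param replication_mode if `TRUE`, normalization and feature selection
#'   use the whole dataset before resampling (the original analysis'
#'   acknowledged information leak); if `FALSE` selection runs inside each
#'   outer training set.
#' @param stages character vector of stages to run.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       extraction = extraction_config(),
                       selection = selection_config(n_resamples = 100),
                       resampling = resampling_spec(outer_reps = 50, inner_reps = 10),
                       grid = default_grid(),
                       k_clusters = 4,
                       replication_mode = TRUE,
                       stages = c("simulate", "extract", "select",
                                  "evaluate_survival", "evaluate_recurrence",
                                  "cluster", "report")) {
  structure(list(cohort = cohort, extraction = extraction, selection = selection,
                 resampling = resampling, grid = as.data.frame(grid),
                 k_clusters = k_clusters, replication_mode = replication_mode,
                 stages = stages),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param file YAML path.
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), file)
  invisible(file)
}

#' @rdname run_config
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  cfg <- run_config(
    cohort = do.call(cohort_spec, y$cohort[setdiff(names(y$cohort), "texture_params")] |>
                       c(list(texture_params = y$cohort$texture_params))),
    extraction = do.call(extraction_config, y$extraction),
    selection = do.call(selection_config, y$selection[names(y$selection) %in%
                                                        names(formals(selection_config))]),
    resampling = do.call(resampling_spec, y$resampling),
    grid = dplyr::bind_rows(lapply(seq_along(y$grid[[1]]), function(i)
      lapply(y$grid, `[[`, i))),
    k_clusters = y$k_clusters,
    replication_mode = y$replication_mode,
    stages = y$stages)
  cfg
}

#' Run the full radiomic analysis pipeline
#'
#' Executes the configured stages, checkpointing each stage's artifacts in
#' `outdir` (features as CSV, selection reports as CSV+JSON, metric dumps as
#' CSV, summary as JSON, a line-oriented run log). Stages that are switched
#' off read their inputs from existing checkpoints, so expensive stages
#' (extraction) can be reused while later stages are iterated.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @param verbose log to console as well as to the run log.
#' @return Invisible list with the in-memory artifacts of the executed run.
#' @export
run_pipeline <- function(config = run_config(), outdir = "radprog_run",
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  log_line <- function(level, ...) {
    msg <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   level, paste0(...))
    cat(msg, "\n", file = logf, append = TRUE)
    if (verbose) message(msg)
  }
  has <- function(stage) stage %in% config$stages
  art <- list()
  feat_csv <- file.path(outdir, "features.csv")
  cohort_dir <- file.path(outdir, "cohort")

  if (has("simulate")) {
    log_line("INFO", "simulate: n = ", config$cohort$n_patients,
             ", seed = ", config$cohort$seed)
    art$cohort <- generate_cohort(config$cohort)
    write_cohort(art$cohort, cohort_dir)
  } else if (dir.exists(cohort_dir)) {
    log_line("INFO", "simulate: skipped, reusing ", cohort_dir)
    art$cohort <- generate_cohort(config$cohort)  # regenerate from spec (deterministic)
  }

  if (has("extract")) {
    log_line("INFO", "extract: 841-feature panel")
    art$features <- extract_cohort(art$cohort, config$extraction)
    write.csv(art$features, feat_csv, row.names = FALSE)
  } else if (file.exists(feat_csv)) {
    log_line("INFO", "extract: skipped, reading ", feat_csv)
    art$features <- tibble::as_tibble(read.csv(feat_csv, check.names = FALSE))
  }

  outc <- art$cohort$outcomes
  norm <- if (!is.null(art$features)) normalize_features(art$features)

  if (has("select")) {
    if (is.null(norm)) stop("run_pipeline: select stage needs features ",
                            "(run extract or provide features.csv)")
    log_line("INFO", "select: survival endpoint")
    art$sel_surv <- resampled_selection(norm, times = outc$time,
                                        events = outc$event,
                                        config = config$selection)
    write_selection_report(art$sel_surv,
                           csv = file.path(outdir, "selection_survival.csv"),
                           json = file.path(outdir, "selection_survival.json"))
    log_line("INFO", "select: recurrence endpoint")
    art$sel_rec <- resampled_selection(norm, labels = outc$recurrence,
                                       config = config$selection)
    write_selection_report(art$sel_rec,
                           csv = file.path(outdir, "selection_recurrence.csv"),
                           json = file.path(outdir, "selection_recurrence.json"))
  } else {
    # reuse selection checkpoints when the stage is toggled off
    for (ep in c("survival", "recurrence")) {
      js <- file.path(outdir, paste0("selection_", ep, ".json"))
      if (file.exists(js)) {
        payload <- jsonlite::read_json(js, simplifyVector = TRUE)
        slot <- if (ep == "survival") "sel_surv" else "sel_rec"
        art[[slot]] <- list(final_signature = payload$final_signature)
        log_line("INFO", "select: skipped, reusing ", js)
      }
    }
  }

  clin <- clinical_features(art$cohort$clinical)
  model_table <- if (!is.null(norm))
    dplyr::bind_cols(norm[, setdiff(names(norm), "patient_id")], clin)

  eval_endpoint <- function(endpoint) {
    surv <- endpoint == "survival"
    sig <- if (surv) art$sel_surv$final_signature else art$sel_rec$final_signature
    args0 <- if (surv) list(times = outc$time, events = outc$event)
             else list(labels = outc$recurrence)
    run1 <- function(feature_set, always = character(0), label) {
      log_line("INFO", "evaluate ", endpoint, ": ", label, " model")
      do.call(nested_evaluate,
              c(list(features = model_table, feature_set = feature_set,
                     always_include = always, spec = config$resampling,
                     grid = config$grid), args0))
    }
    list(clinical = run1(names(clin), character(0), "clinical"),
         radiomic = run1(sig, character(0), "radiomic"),
         combined = run1(sig, names(clin), "combined"))
  }

  if (has("evaluate_survival")) {
    res <- eval_endpoint("survival")
    art$surv_models <- res
    art$surv_comparison <- compare_models(clinical = res$clinical,
                                          radiomic = res$radiomic,
                                          combined = res$combined)
    write.csv(art$surv_comparison$raw, file.path(outdir, "metrics_survival.csv"),
              row.names = FALSE)
    km <- lapply(res, risk_stratification, times = outc$time, events = outc$event)
    art$km <- km
    for (nm in names(km))
      write.csv(km[[nm]]$curves,
                file.path(outdir, paste0("km_", nm, ".csv")), row.names = FALSE)
  }

  if (has("evaluate_recurrence")) {
    res <- eval_endpoint("recurrence")
    art$rec_models <- res
    art$rec_comparison <- compare_models(clinical = res$clinical,
                                         radiomic = res$radiomic,
                                         combined = res$combined)
    write.csv(art$rec_comparison$raw, file.path(outdir, "metrics_recurrence.csv"),
              row.names = FALSE)
  }

  if (has("cluster")) {
    if (is.null(norm)) stop("run_pipeline: cluster stage needs features")
    log_line("INFO", "cluster: two-way UPGMA, k = ", config$k_clusters)
    art$clusters <- two_way_cluster(norm, config$k_clusters)
    art$associations <- cluster_association(art$clusters, art$cohort$clinical)
    write.csv(art$associations, file.path(outdir, "cluster_associations.csv"),
              row.names = FALSE)
    write_heatmap_data(art$clusters, norm, file.path(outdir, "heatmap_matrix.csv"))
  }

  if (has("report")) {
    summary <- list(
      n_patients = config$cohort$n_patients,
      n_features = length(panel_feature_names()),
      survival_signature = if (!is.null(art$sel_surv)) art$sel_surv$final_signature,
      recurrence_signature = if (!is.null(art$sel_rec)) art$sel_rec$final_signature,
      survival = if (!is.null(art$surv_comparison)) art$surv_comparison$summary,
      recurrence = if (!is.null(art$rec_comparison)) art$rec_comparison$summary,
      cluster_associations = art$associations,
      seeds = list(cohort = config$cohort$seed,
                   selection = config$selection$seed,
                   resampling = config$resampling$seed))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_run_config(config, file.path(outdir, "config.yml"))
    log_line("INFO", "report written to ", file.path(outdir, "summary.json"))
  }
  invisible(art)
}
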