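make_tiny_cohort <- function(n = 45, seed = 1) {
  set.seed(seed)
  list(X = tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n)),
       time = rexp(n, 0.01), event = {e <- rbinom(n, 1, 0.8); e[1:4] <- 1L; e},
       labels = {y <- rbinom(n, 1, 0.5); y[1:2] <- c(0L, 1L); y})
}

one_row_grid <- tibble::tibble(n_stages = 10L, learning_rate = 0.2,
                               max_depth = 2L, min_leaf = 5L)

test_that("outer folds partition the cohort and metrics are conserved", {
  d <- make_tiny_cohort()
  spec <- resampling_spec(outer_reps = 6, outer_folds = 3, inner_reps = 1,
                          inner_folds = 3, seed = 2)
  r <- nested_evaluate(d$X, times = d$time, events = d$event,
                       feature_set = c("a", "b"), spec = spec,
                       grid = one_row_grid)
  expect_equal(nrow(r$results) + nrow(r$excluded), 6L * 3L)
  # per rep, test folds are disjoint and exhaustive
  for (rp in unique(r$predictions$rep)) {
    idx <- r$predictions$index[r$predictions$rep == rp]
    expect_equal(sort(idx), seq_len(nrow(d$X)))
  }
  expect_true(all(r$results$ci >= 0 & r$results$ci <= 1))
})

test_that("nested evaluation is reproducible under a fixed seed", {
  d <- make_tiny_cohort(seed = 3)
  spec <- resampling_spec(outer_reps = 4, outer_folds = 3, inner_reps = 2,
                          inner_folds = 3, seed = 7)
  r1 <- nested_evaluate(d$X, times = d$time, events = d$event,
                        feature_set = c("a", "b", "c"), spec = spec)
  r2 <- nested_evaluate(d$X, times = d$time, events = d$event,
                        feature_set = c("a", "b", "c"), spec = spec)
  expect_identical(r1$results, r2$results)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("models under the same spec share outer folds (paired comparison)", {
  d <- make_tiny_cohort(seed = 4)
  spec <- resampling_spec(outer_reps = 3, outer_folds = 3, inner_reps = 1,
                          inner_folds = 3, seed = 5)
  ra <- nested_evaluate(d$X, times = d$time, events = d$event,
                        feature_set = "a", spec = spec, grid = one_row_grid)
  rb <- nested_evaluate(d$X, times = d$time, events = d$event,
                        feature_set = c("b", "c"), spec = spec, grid = one_row_grid)
  fold_of <- function(r) dplyr::arrange(r$predictions, .data$rep, .data$index)[,
    c("rep", "index", "fold")]
  expect_identical(fold_of(ra), fold_of(rb))
})

test_that("no test patient is seen by the fit that scores it", {
  # ids flow through predictions: every (rep, fold) block predicts exactly
  # the patients of that fold, none of which were in its training split
  d <- make_tiny_cohort(seed = 6)
  spec <- resampling_spec(outer_reps = 2, outer_folds = 3, inner_reps = 1,
                          inner_folds = 3, seed = 8)
  r <- nested_evaluate(d$X, times = d$time, events = d$event,
                       feature_set = c("a", "b"), spec = spec, grid = one_row_grid)
  per_fold <- split(r$predictions$index,
                    paste(r$predictions$rep, r$predictions$fold))
  for (rp in unique(r$predictions$rep)) {
    blocks <- per_fold[startsWith(names(per_fold), paste0(rp, " "))]
    expect_equal(length(Reduce(intersect, blocks)), 0L)
  }
})

test_that("recurrence evaluation returns both AUC and AUPRC per fold", {
  d <- make_tiny_cohort(seed = 9)
  spec <- resampling_spec(outer_reps = 4, outer_folds = 3, inner_reps = 1,
                          inner_folds = 3, seed = 10)
  r <- nested_evaluate(d$X, labels = d$labels, feature_set = c("a", "b"),
                       spec = spec, grid = one_row_grid)
  expect_true(all(c("auc", "auprc") %in% names(r$results)))
  expect_equal(nrow(r$results) + nrow(r$excluded), 12L)
})

test_that("model comparison summaries are recomputable from the raw dump", {
  d <- make_tiny_cohort(seed = 11)
  spec <- resampling_spec(outer_reps = 3, outer_folds = 3, inner_reps = 1,
                          inner_folds = 3, seed = 12)
  ra <- nested_evaluate(d$X, times = d$time, events = d$event,
                        feature_set = "a", spec = spec, grid = one_row_grid)
  cmp <- compare_models(clinical = ra, radiomic = ra)
  s <- cmp$summary
  expect_equal(s$mean[s$model == "clinical"], s$mean[s$model == "radiomic"])
  by_hand <- as.numeric(tapply(cmp$raw$value, cmp$raw$model, mean))
  expect_equal(sort(by_hand), sort(s$mean))
})

test_that("risk stratification averages per-patient risks before the median split", {
  d <- make_tiny_cohort(seed = 13)
  spec <- resampling_spec(outer_reps = 5, outer_folds = 3, inner_reps = 1,
                          inner_folds = 3, seed = 14)
  r <- nested_evaluate(d$X, times = d$time, events = d$event,
                       feature_set = c("a", "b"), spec = spec, grid = one_row_grid)
  km <- risk_stratification(r, d$time, d$event)
  expect_s3_class(km, "km_strata")
  expect_setequal(unique(km$curves$group), c("low", "high"))
  # survivor curves start at/below 1 and are nonincreasing within group
  for (g in c("low", "high")) {
    sv <- km$curves$surv[km$curves$group == g]
    expect_true(all(diff(sv) <= 1e-12))
    expect_lte(max(sv), 1)
  }
})
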