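test_that("zero noise and zero factors give a constant-intensity ellipsoid", {
  tp <- list(field_sd = 0, coarse_sd = 0, white_sd = 0)
  ph <- generate_phantom(c(0, 0, 0), c(20, 20, 20), tp, seed = 2)
  inside <- ph$mask == 1
  expect_gte(sum(inside), 27)
  expect_equal(sd(ph$volume[inside]), 0)
  roi <- discretize(ph$volume, ph$mask, 25)
  expect_equal(unname(glcm_features(roi)["Contrast"]), 0)
})

test_that("phantom generation is bit-reproducible under a fixed seed", {
  a <- generate_phantom(c(1, -1, 0), c(18, 18, 18), seed = 77)
  b <- generate_phantom(c(1, -1, 0), c(18, 18, 18), seed = 77)
  expect_identical(a, b)
  spec <- cohort_spec(n_patients = 8, image_shape = c(18L, 18L, 18L), seed = 5)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
})

test_that("latent factors shift texture distributions by more than one SD", {
  contrast_at <- function(z1, s) {
    ph <- generate_phantom(c(z1, 0, 0), c(20, 20, 20), seed = s)
    roi <- discretize(ph$volume, ph$mask, 25)
    unname(glcm_features(roi)["Contrast"])
  }
  lo <- vapply(1:50, function(s) contrast_at(-2, s), numeric(1))
  hi <- vapply(1:50, function(s) contrast_at(2, 100 + s), numeric(1))
  pooled_sd <- sqrt((var(lo) + var(hi)) / 2)
  expect_gt(abs(mean(lo) - mean(hi)) / pooled_sd, 1)
})

test_that("null effects leave survival uncorrelated with the factors", {
  spec <- cohort_spec(n_patients = 200, image_shape = c(16L, 16L, 16L),
                      effect_sizes = c(0, 0, 0), censor_rate = 0, seed = 12)
  coh <- generate_cohort(spec)
  tau <- cor(coh$latent[, 1], coh$outcomes$time, method = "kendall")
  expect_lt(abs(tau), 0.1)
})

test_that("the survival generator is recovered by a Cox fit on the true factors", {
  spec <- cohort_spec(n_patients = 500, image_shape = c(16L, 16L, 16L),
                      effect_sizes = c(1, 0, 0), censor_rate = 0, seed = 31)
  coh <- generate_cohort(spec)
  fit <- survival::coxph(survival::Surv(coh$outcomes$time, coh$outcomes$event) ~
                           coh$latent[, 1])
  beta <- unname(coef(fit)); se <- sqrt(unname(vcov(fit)[1, 1]))
  expect_gt(beta, 0)
  expect_lt(abs(beta - 1), 2 * se)
})

test_that("uniform censoring is calibrated to the requested rate", {
  spec <- cohort_spec(n_patients = 500, image_shape = c(16L, 16L, 16L),
                      censor_rate = 0.3, seed = 41)
  coh <- generate_cohort(spec)
  expect_equal(1 - mean(coh$outcomes$event), 0.3, tolerance = 0.05)
  expect_true(all(coh$outcomes$time > 0))
})

test_that("clinical covariates follow the documented marginals, independent of outcome", {
  spec <- cohort_spec(n_patients = 600, image_shape = c(16L, 16L, 16L), seed = 51)
  coh <- generate_cohort(spec)
  cl <- coh$clinical
  expect_equal(mean(cl$gender), 0.608, tolerance = 0.06)
  expect_equal(mean(cl$n_stage), 0.446, tolerance = 0.06)
  expect_equal(mean(cl$site == 0), 0.797, tolerance = 0.06)
  expect_true(all(cl$t_stage %in% 0:2), TRUE)
  # independence from the planted factors
  expect_lt(abs(cor(cl$gender, coh$latent[, 1])), 0.12)
  expect_lt(abs(cor(cl$resection, coh$latent[, 2])), 0.12)
})

test_that("cohorts round-trip to disk (NRRD + CSV + JSON manifest)", {
  spec <- cohort_spec(n_patients = 6, image_shape = c(16L, 16L, 16L), seed = 9)
  coh <- generate_cohort(spec)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "P001_volume.nrrd")))
  v <- read_volume(file.path(dir, "P002_volume.nrrd"))
  expect_equal(v$data, coh$volumes[[2]], tolerance = 1e-12)
  cl <- read.csv(file.path(dir, "clinical.csv"))
  expect_equal(nrow(cl), 6L)
  mani <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_equal(mani$spec$seed, 9L)
  unlink(dir, recursive = TRUE)
})
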