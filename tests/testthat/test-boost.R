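test_that("a 0-stage Cox ensemble is a constant-risk model", {
  d <- surv_sim(60, seed = 23)
  m <- fit_boosted_cox(data.frame(x = d$x), d$time, d$event,
                       list(n_stages = 0))
  r <- predict(m, data.frame(x = d$x))
  expect_true(all(r == r[1]))
  expect_equal(suppressWarnings(as.numeric(concordance_index(r, d$time, d$event))),
               0.5)
})

test_that("a boosted Cox model on the true log-hazard ranks held-out patients", {
  set.seed(24)
  n <- 300
  x <- rnorm(n)
  eta <- 2.5 * x                       # strong planted hazard
  t_true <- rexp(n) / (0.01 * exp(eta))
  cmax <- uniroot(function(cc) mean(pmin(t_true / cc, 1)) - 0.2,
                  c(1e-4, max(t_true) * 100))$root
  cens <- runif(n, 0, cmax)
  tt <- pmin(t_true, cens); ee <- as.integer(t_true <= cens)
  tr <- 1:200; te <- 201:300
  m <- fit_boosted_cox(data.frame(x = x[tr]), tt[tr], ee[tr],
                       list(n_stages = 100, learning_rate = 0.1))
  ci <- as.numeric(concordance_index(predict(m, data.frame(x = x[te])),
                                     tt[te], ee[te]))
  expect_gt(ci, 0.85)
})

test_that("training loss is nonincreasing and predictions are feature-order invariant", {
  set.seed(25)
  n <- 120
  X <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  tt <- rexp(n, exp(0.5 * X$a)); ee <- rbinom(n, 1, 0.8); ee[1:2] <- 1L
  m <- fit_boosted_cox(X, tt, ee, list(n_stages = 60))
  expect_true(all(diff(m$train_loss) <= 1e-9))
  m2 <- fit_boosted_cox(X[, c("c", "a", "b")], tt, ee, list(n_stages = 60))
  expect_equal(predict(m, X), predict(m2, X), tolerance = 1e-12)
  # logistic loss path too
  y <- rbinom(n, 1, plogis(X$a))
  mc <- fit_boosted_classifier(X, y, list(n_stages = 60))
  expect_true(all(diff(mc$train_loss) <= 1e-9))
})

test_that("a 0-stage classifier scores everyone at the prevalence", {
  set.seed(26)
  X <- tibble::tibble(x = rnorm(50))
  y <- rbinom(50, 1, 0.3); y[1:2] <- c(0L, 1L)
  m <- fit_boosted_classifier(X, y, list(n_stages = 0))
  expect_equal(unique(predict(m, X, type = "response")), mean(y),
               tolerance = 1e-12)
})

test_that("a separable planted signal yields high held-out AUC", {
  set.seed(27)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- as.integer(x1 + x2 + rnorm(n, 0, 0.3) > 0)
  tr <- 1:200; te <- 201:300
  m <- fit_boosted_classifier(tibble::tibble(x1 = x1[tr], x2 = x2[tr]), y[tr],
                              list(n_stages = 100))
  auc <- roc_auc(predict(m, tibble::tibble(x1 = x1[te], x2 = x2[te])), y[te])
  expect_gt(auc, 0.9)
})

test_that("label flip mirrors the ranking", {
  set.seed(28)
  n <- 150
  X <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  y <- as.integer(X$x1 + rnorm(n, 0, 0.5) > 0)
  m1 <- fit_boosted_classifier(X, y, list(n_stages = 50))
  m2 <- fit_boosted_classifier(X, 1L - y, list(n_stages = 50))
  s1 <- predict(m1, X); s2 <- predict(m2, X)
  expect_lt(cor(s1, s2, method = "spearman"), -0.9)
  expect_equal(roc_auc(s1, y), roc_auc(s2, 1L - y), tolerance = 0.05)
})

test_that("ensembles serialize to JSON and predict identically after reload", {
  d <- surv_sim(80, beta_sd = 1, seed = 29)
  X <- data.frame(x = d$x, z = rnorm(80))
  m <- fit_boosted_cox(X, d$time, d$event, list(n_stages = 20))
  f <- tempfile(fileext = ".json")
  write_boost_json(m, f)
  m2 <- read_boost_json(f)
  expect_equal(predict(m, X), predict(m2, X), tolerance = 1e-12)
  unlink(f)
})

test_that("prediction is additive in boosting stages", {
  d <- surv_sim(100, seed = 30)
  X <- data.frame(x = d$x)
  m <- fit_boosted_cox(X, d$time, d$event, list(n_stages = 40))
  p10 <- predict(m, X, n_stages = 10)
  p40 <- predict(m, X, n_stages = 40)
  expect_false(isTRUE(all.equal(p10, p40)))
  expect_equal(predict(m, X), p40)
})
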