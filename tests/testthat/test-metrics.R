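test_that("concordance index matches exhaustive pair enumeration", {
  # toy case with censoring: 6 pairs, enumerated in the helper oracle
  ci <- concordance_index(c(0.9, 0.1, 0.8, 0.2), c(2, 4, 6, 8), c(1, 0, 1, 1))
  expect_equal(as.numeric(ci), bf_concordance(c(0.9, 0.1, 0.8, 0.2),
                                              c(2, 4, 6, 8), c(1, 0, 1, 1)))
  set.seed(5)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    r <- rnorm(n)
    if (i %% 3 == 0) r <- round(r, 1)          # provoke risk ties
    tt <- sample(1:12, n, replace = TRUE)      # provoke time ties
    ee <- rbinom(n, 1, 0.6)
    if (sum(ee) == 0) ee[1] <- 1L
    a <- suppressWarnings(as.numeric(concordance_index(r, tt, ee)))
    expect_equal(a, bf_concordance(r, tt, ee))
  }
})

test_that("concordance satisfies the anti-symmetry and tie conventions", {
  set.seed(6)
  tt <- rexp(40); ee <- rbinom(40, 1, 0.7); r <- rnorm(40)
  a <- as.numeric(concordance_index(r, tt, ee))
  b <- as.numeric(concordance_index(-r, tt, ee))
  expect_equal(a + b, 1)
  expect_equal(as.numeric(concordance_index(rep(1, 40), tt, ee)), 0.5)
  # perfect anti-ordering, all events
  expect_equal(as.numeric(concordance_index(10:1, 1:10, rep(1, 10))), 1)
})

test_that("AUC equals Mann-Whitney pair counting, with 0.5 for ties", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(8)
  for (i in 1:100) {
    n <- sample(6:50, 1)
    s <- round(rnorm(n), 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    expect_equal(roc_auc(s, y), bf_auc(s, y))
  }
  # invariance under strictly monotone transform
  s <- rnorm(60); y <- rbinom(60, 1, 0.4); y[1:2] <- c(0L, 1L)
  expect_equal(roc_auc(s, y), roc_auc(exp(2 * s) + 3, y))
})

test_that("AUC agrees with an independent implementation and the null level", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- rnorm(200); y <- rbinom(200, 1, 0.5)
  expect_equal(roc_auc(s, y),
               as.numeric(suppressMessages(pROC::auc(y, s, direction = "<"))))
  s2 <- rnorm(2000); y2 <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(s2, y2) - 0.5), 0.03)
})

test_that("AUPRC uses precision steps and equals prevalence for a flat scorer", {
  expect_equal(pr_auprc(c(3, 2, 1, 0), c(1, 1, 0, 0)), 1)
  y <- c(1, 0, 0, 1, 0, 1, 0, 0, 0, 1)
  expect_equal(pr_auprc(rep(0.5, 10), y), mean(y))
  # hand-computed small case: scores sorted desc 0.9(1) 0.7(0) 0.6(1) 0.2(0)
  # recall steps 0.5 at prec 1, then 1.0 at prec 2/3
  expect_equal(pr_auprc(c(0.9, 0.7, 0.6, 0.2), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_gte(pr_auprc(rnorm(50), rbinom(50, 1, 0.3) | c(1, rep(0, 49))), 0)
})

test_that("Kaplan-Meier without censoring is the empirical survivor function", {
  tt <- c(1, 2, 3, 4, 5); ee <- rep(1L, 5)
  km <- stratify_and_km(c(1, 2, 3, 4, 5), tt, ee)
  low <- km$curves[km$curves$group == "low", ]
  expect_equal(low$surv, 1 - seq_along(low$time) / nrow(low))
})

test_that("log-rank statistic matches the hand-computed table", {
  # groups {1,2,3} all events vs {4,5,6} all events; expected counts follow
  # the standard observed-minus-expected tally:
  # O1 = 3; E1 = 1/2 + 2/5 + 1/4 = 1.15; V = sum of hypergeometric variances
  tt <- c(1, 2, 3, 4, 5, 6); ee <- rep(1L, 6)
  risks <- c(10, 9, 8, 1, 2, 3)  # high group = early deaths
  km <- stratify_and_km(risks, tt, ee)
  V <- 0.25 + 6 / 25 + 3 / 16
  expect_equal(km$logrank_chisq, (3 - 1.15)^2 / V, tolerance = 1e-10)
  # identical groups: statistic 0, p = 1
  tt2 <- rep(c(1, 2, 3, 4), 2); ee2 <- rep(1L, 8)
  km2 <- stratify_and_km(c(1, 1, 2, 2, 3, 3, 4, 4), tt2, ee2)
  expect_equal(km2$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(km2$logrank_p, 1)
})

test_that("averaged KM curves are pointwise means on the common grid", {
  c1 <- tibble::tibble(group = "low", time = c(1, 3), surv = c(0.8, 0.4))
  c2 <- tibble::tibble(group = "low", time = c(2, 4), surv = c(0.6, 0.2))
  avg <- average_km(list(c1, c2), grid = c(0, 1.5, 2.5, 3.5, 4.5))
  expect_equal(avg$surv, c(1, 0.9, 0.7, 0.5, 0.3))
  one <- average_km(list(c1), grid = c(0, 1, 2, 3))
  expect_equal(one$surv, c(1, 0.8, 0.8, 0.4))
  two <- average_km(list(c1, c1), grid = c(0.5, 2))
  expect_equal(two$surv, c(1, 0.8))
})
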