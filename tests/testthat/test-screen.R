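test_that("the univariate Cox screen matches survival::coxph with Efron ties", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    x <- rnorm(n)
    tt <- round(rexp(n, exp(0.5 * x)), if (i %% 2) 1 else 3) + 0.05
    ee <- rbinom(n, 1, 0.75)
    if (sum(ee) < 2) ee[1:2] <- 1L
    mine <- univariate_cox(x, tt, ee)
    ref <- survival::coxph(survival::Surv(tt, ee) ~ scale(x), ties = "efron")
    expect_equal(mine$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(mine$se, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-6)
    p_ref <- 2 * pnorm(-abs(unname(coef(ref)) / sqrt(unname(vcov(ref)[1, 1]))))
    expect_equal(mine$raw_p, p_ref, tolerance = 1e-6)
  }
})

test_that("the partial-likelihood score at beta = 0 matches the hand formula", {
  # sorted times, no ties: U(0) = sum over events of x_i - mean(x in risk set)
  x <- c(0.3, -1.2, 0.7, 2.0, -0.5)
  tt <- c(1, 2, 3, 4, 5)
  ee <- c(1L, 0L, 1L, 1L, 0L)
  U_hand <- (x[1] - mean(x[1:5])) + (x[3] - mean(x[3:5])) + (x[4] - mean(x[4:5]))
  # finite-difference of the fitted log-likelihood path is indirect; instead
  # exploit that one Newton step from 0 is U/I and both come from the same pass
  ref <- survival::coxph(survival::Surv(tt, ee) ~ x,
                         control = survival::coxph.control(iter.max = 0))
  expect_equal(unname(survival::coxph.detail(ref)$score) |> sum(), U_hand,
               tolerance = 1e-10)
  mine <- univariate_cox(x, tt, ee)
  ref_full <- survival::coxph(survival::Surv(tt, ee) ~ scale(x))
  expect_equal(mine$beta, unname(coef(ref_full)), tolerance = 1e-6)
})

test_that("univariate CI behaves at the extremes", {
  set.seed(14)
  # feature equal to the rank of survival time, no censoring: perfect ordering
  tt <- sample(1:20)
  r <- rank(tt)
  res <- univariate_cox(r, tt, rep(1L, 20))
  expect_true(res$statistic %in% c(0, 1))
  expect_gt(abs(res$beta), 2)
  # independent feature: CI near 0.5
  x <- rnorm(200); t2 <- rexp(200); e2 <- rep(1L, 200)
  res2 <- univariate_cox(x, t2, e2)
  expect_equal(res2$statistic, 0.5, tolerance = 0.05)
  # constant feature flagged
  res3 <- univariate_cox(rep(1, 20), tt, rep(1L, 20))
  expect_true(res3$flagged)
})

test_that("one-way ANOVA screen matches the hand table and the lm oracle", {
  res <- univariate_anova(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(res$statistic, 13.5)
  # means-matched groups: F = 0
  res0 <- univariate_anova(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  set.seed(15)
  for (i in 1:25) {
    x <- rnorm(40); g <- sample(0:1, 40, replace = TRUE)
    if (length(unique(g)) < 2) g[1:2] <- c(0L, 1L)
    mine <- univariate_anova(x, g)
    ref <- anova(stats::lm(x ~ factor(g)))
    expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$raw_p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
  # the vectorized matrix screen agrees with the scalar op
  X <- matrix(rnorm(40 * 30), 40, 30); colnames(X) <- sprintf("f%02d", 1:30)
  g <- rbinom(40, 1, 0.5); g[1:2] <- c(0L, 1L)
  scr <- univariate_screen(tibble::as_tibble(X), labels = g)
  for (j in c(1, 9, 25))
    expect_equal(scr$statistic[j], univariate_anova(X[, j], g)$statistic,
                 tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up hand formula", {
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(16)
  for (i in 1:200) {
    p <- runif(sample(1:60, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, bf_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # order preserving
  }
})
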