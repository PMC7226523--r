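test_that("correlation pruning resolves redundant pairs deterministically", {
  set.seed(17)
  x <- rnorm(50)
  X <- tibble::tibble(a = x, b = x, c = rnorm(50))
  sc <- c(a = 3, b = 2, c = 1)
  expect_identical(correlation_prune(X, sc, 0.8), c("a", "c"))  # duplicate: keep stronger
  # 3 features, r(1,2) high, r(1,3) low, scores 1 > 2: drop feature 2
  X2 <- tibble::tibble(f1 = x, f2 = x + rnorm(50, 0, 0.2), f3 = rnorm(50))
  stopifnot(abs(cor(X2$f1, X2$f2)) > 0.9, abs(cor(X2$f1, X2$f3)) < 0.5)
  expect_identical(correlation_prune(X2, c(f1 = 5, f2 = 4, f3 = 1), 0.8),
                   c("f1", "f3"))
  # orthogonal features all survive
  X3 <- tibble::as_tibble(as.data.frame(qr.Q(qr(matrix(rnorm(100), 20, 5)))))
  sc3 <- setNames(1:5, names(X3))
  expect_identical(correlation_prune(X3, sc3, 0.8), names(X3))
  # score tie resolved by name order
  X4 <- tibble::tibble(zz = x, aa = x)
  expect_identical(correlation_prune(X4, c(zz = 1, aa = 1), 0.8), "aa")
})

test_that("pruning output is threshold-monotone and mutually decorrelated", {
  set.seed(18)
  n <- 60
  base <- matrix(rnorm(n * 4), n, 4)
  X <- cbind(base, base[, 1] + rnorm(n, 0, 0.3), base[, 2] + rnorm(n, 0, 0.1),
             matrix(rnorm(n * 4), n, 4))
  colnames(X) <- sprintf("v%02d", seq_len(ncol(X)))
  X <- tibble::as_tibble(as.data.frame(X))
  sc <- setNames(runif(ncol(X)), names(X))
  prev <- character(0)
  for (thr in c(0.5, 0.7, 0.9, 0.99)) {
    surv <- correlation_prune(X, sc, thr)
    cm <- abs(cor(as.matrix(X[, surv]))); diag(cm) <- 0
    expect_lte(max(cm), thr)                 # no surviving pair above threshold
    expect_true(all(prev %in% surv))         # higher threshold => superset
    prev <- surv
  }
})

test_that("SFFS finds optima that plain greedy forward misses", {
  # lookup-table objective where the best pair {B,C} is invisible to greedy
  tab <- c("A" = 0.50, "B" = 0.40, "C" = 0.40,
           "A,B" = 0.60, "A,C" = 0.60, "B,C" = 1.00, "A,B,C" = 0.90)
  obj <- function(s) {
    key <- paste(sort(s), collapse = ",")
    if (key %in% names(tab)) tab[[key]] else 0
  }
  out <- sffs(c("A", "B", "C"), obj, max_size = 3)
  expect_setequal(as.character(out), c("B", "C"))
  expect_equal(attr(out, "score"), 1.0)
  # exhaustive cross-check over all non-empty subsets
  subsets <- unlist(lapply(1:3, function(k)
    combn(c("A", "B", "C"), k, simplify = FALSE)), recursive = FALSE)
  best <- max(vapply(subsets, obj, numeric(1)))
  expect_equal(attr(out, "score"), best)
})

test_that("SFFS selects a dominant feature first and respects max_size", {
  vals <- c(big = 10, s1 = 1, s2 = 2, s3 = 3)
  additive <- function(s) sum(vals[s])
  out <- sffs(names(vals), additive, max_size = 2)
  expect_true("big" %in% out)
  expect_lte(length(out), 2)
  # monotone objective: runs to max_size and scores >= greedy
  set.seed(19)
  w <- setNames(runif(6), letters[1:6])
  mono <- function(s) sum(w[s])
  out2 <- sffs(names(w), mono, max_size = 4)
  expect_equal(length(out2), 4)
})

test_that("SFFS never scores below greedy forward selection", {
  set.seed(20)
  for (rep_i in 1:10) {
    feats <- letters[1:5]
    w <- setNames(rnorm(5), feats)
    inter <- matrix(rnorm(25, 0, 0.8), 5, 5, dimnames = list(feats, feats))
    inter <- (inter + t(inter)) / 2; diag(inter) <- 0
    obj <- function(s) sum(w[s]) + sum(inter[s, s]) / 2
    greedy <- character(0)
    for (k in 1:3) {
      rem <- setdiff(feats, greedy)
      gains <- vapply(rem, function(f) obj(c(greedy, f)), numeric(1))
      greedy <- c(greedy, rem[which.max(gains)])
    }
    greedy_best <- max(vapply(1:3, function(k) obj(greedy[1:k]), numeric(1)))
    out <- sffs(feats, obj, max_size = 3)
    expect_gte(attr(out, "score"), greedy_best - 1e-12)
  }
})

test_that("resampled selection recovers planted signal and is reproducible", {
  set.seed(21)
  n <- 120
  z <- matrix(rnorm(n * 3), n, 3)
  tt <- rexp(n) / (0.002 * exp(z %*% c(1, 1, 1)))
  ee <- rep(1L, n)
  X <- as.data.frame(matrix(rnorm(n * 80), n, 80))
  names(X) <- sprintf("noise%02d", 1:80)
  X$sig1 <- z[, 1] + rnorm(n, 0, 0.3)
  X$sig2 <- z[, 2] + rnorm(n, 0, 0.3)
  X$sig3 <- z[, 3] + rnorm(n, 0, 0.3)
  X <- tibble::as_tibble(X)
  cfg <- selection_config(n_resamples = 40, seed = 3)
  sel <- resampled_selection(X, times = tt, events = ee, config = cfg)
  top5 <- head(sel$frequencies$feature, 5)
  expect_true(all(c("sig1", "sig2", "sig3") %in% top5))
  expect_true(all(sel$final_signature %in% sel$frequencies$feature))
  expect_true(all(sel$frequencies$frequency >= 0 & sel$frequencies$frequency <= 1))
  # determinism under the same seed
  sel2 <- resampled_selection(X, times = tt, events = ee, config = cfg)
  expect_identical(sel$final_signature, sel2$final_signature)
  expect_identical(sel$frequencies, sel2$frequencies)
})

test_that("pure-noise frequencies stay clearly below planted-signal levels", {
  # on a fixed dataset a by-chance associated noise feature is re-selected in
  # a sizable share of subsamples; what separates signal from noise is that
  # planted features approach frequency 1 while noise does not, and the bulk
  # of noise features are rarely selected
  set.seed(22)
  n <- 120
  X <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 120), n, 120)))
  names(X) <- sprintf("n%03d", 1:120)
  tt <- rexp(n, 0.01); ee <- rbinom(n, 1, 0.9)
  sel <- resampled_selection(X, times = tt, events = ee,
                             config = selection_config(n_resamples = 60, seed = 4))
  expect_lt(max(sel$frequencies$frequency), 0.9)
  expect_lt(mean(sel$frequencies$frequency), 0.06)
  expect_lt(sort(sel$frequencies$frequency, decreasing = TRUE)[10], 0.3)
})
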