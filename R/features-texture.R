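# Texture feature classes on a discretized ROI, following the IBSI reference
# definitions. Matrix construction is done in C++ (see src/texture.cpp); the
# feature formulas live here. GLCM and GLRLM matrices are built per direction
# (13 unique 3-D directions at distance 1) and feature values are averaged
# across directions; GLSZM/GLDM/NGTDM are single aggregated matrices.
#
# Degenerate-ROI policy: on a single-level ROI, correlation-type quantities
# (GLCM Correlation, MCC) return the sentinel value 1, entropies return 0;
# no feature raises mid-pipeline.

roi_levels <- function(roi) {
  stopifnot(inherits(roi, "discretized_roi"))
  roi$levels
}

#' Gray level co-occurrence matrix features
#'
#' Computes the 23 GLCM features from symmetric, normalized co-occurrence
#' matrices at distance 1, averaged over the 13 unique 3-D directions.
#'
#' @param roi a `discretized_roi` from [discretize()].
#' @return Named numeric vector of 23 features.
#' @export
glcm_features <- function(roi) {
  lev <- roi_levels(roi)
  nvox <- sum(lev > 0)
  if (nvox < 2) return(flagged_na(glcm_feature_names()))
  ng <- roi$n_levels
  counts <- cpp_glcm(lev, dim(lev), ng)
  vals <- matrix(NA_real_, 13, length(glcm_feature_names()))
  used <- 0L
  for (d in seq_len(13)) {
    M <- matrix(counts[, , d], ng, ng)
    tot <- sum(M)
    if (tot == 0) next   # some directions unusable in flat/small ROIs
    used <- used + 1L
    vals[used, ] <- glcm_one(M / tot, ng)
  }
  if (used == 0L) return(flagged_na(glcm_feature_names()))
  setNames(colMeans(vals[seq_len(used), , drop = FALSE]), glcm_feature_names())
}

glcm_feature_names <- function() c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
  "MaximumProbability", "MCC", "SumEntropy", "SumSquares")

glcm_one <- function(p, ng) {
  eps <- the_eps
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx2 <- sum((seq_len(ng) - mux)^2 * px); sy2 <- sum((seq_len(ng) - muy)^2 * py)
  dif <- abs(i - j)
  pd <- vapply(0:(ng - 1), function(k) sum(p[dif == k]), numeric(1))   # p_{x-y}
  ps <- vapply(2:(2 * ng), function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum((0:(ng - 1)) * pd)
  HXY <- -sum(p * log2(p + eps))
  pxpy <- outer(px, py)
  HXY1 <- -sum(p * log2(pxpy + eps))
  HXY2 <- -sum(pxpy * log2(pxpy + eps))
  HX <- -sum(px * log2(px + eps)); HY <- -sum(py * log2(py + eps))
  corr <- if (sx2 * sy2 > 0) (sum(i * j * p) - mux * muy) / sqrt(sx2 * sy2) else 1
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  # MCC: second largest eigenvalue of Q(i,j) = sum_k p(i,k) p(j,k) / (px_i py_k)
  keep <- px > 0
  mcc <- 1
  if (sum(keep) > 1) {
    pk <- p[keep, keep, drop = FALSE]
    pyk <- py[keep]
    A <- pk / px[keep]                       # rows scaled by 1/px
    B <- sweep(pk, 2, pyk, "/")              # columns scaled by 1/py
    Q <- A %*% t(B)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(pmax(ev[2], 0))
  }
  c(sum(i * j * p),
    sum((i + j - mux - muy)^4 * p),
    sum((i + j - mux - muy)^3 * p),
    sum((i + j - mux - muy)^2 * p),
    sum((i - j)^2 * p),
    corr,
    da,
    -sum(pd * log2(pd + eps)),
    sum(((0:(ng - 1)) - da)^2 * pd),
    sum(p / (1 + dif)),
    sum(p / (1 + dif^2)),
    sum(p / (1 + dif^2 / ng^2)),
    sum(p / (1 + dif / ng)),
    imc1, imc2,
    sum(p[dif > 0] / dif[dif > 0]^2),
    mux,
    sum(p^2),
    HXY,
    max(p),
    mcc,
    -sum(ps * log2(ps + eps)),
    sx2)
}

#' Gray level run length matrix features
#'
#' The 16 GLRLM features from run-length matrices over the 13 unique 3-D
#' directions, feature values averaged across directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(roi) {
  lev <- roi_levels(roi)
  nvox <- sum(lev > 0)
  if (nvox < 1) return(flagged_na(glrlm_feature_names()))
  ng <- roi$n_levels
  counts <- cpp_glrlm(lev, dim(lev), ng)
  dd <- dim(counts)
  vals <- matrix(NA_real_, 13, 16)
  for (d in seq_len(13)) {
    P <- matrix(counts[, , d], dd[1], dd[2])
    vals[d, ] <- rl_one(P, nvox)
  }
  setNames(colMeans(vals), glrlm_feature_names())
}

glrlm_feature_names <- function() c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis")

rl_one <- function(P, np) {
  Nr <- sum(P)
  if (Nr == 0) return(rep(NA_real_, 16))
  i <- row(P); r <- col(P)
  p <- P / Nr
  gi <- rowSums(P); rr <- colSums(P)
  mu_i <- sum(i * p); mu_r <- sum(r * p)
  eps <- the_eps
  c(sum(gi^2) / Nr,
    sum(gi^2) / Nr^2,
    sum((i - mu_i)^2 * p),
    sum(i^2 * p),
    sum(r^2 * p),
    sum(i^2 * r^2 * p),
    sum(r^2 / i^2 * p),
    sum(p / i^2),
    -sum(p * log2(p + eps)),
    sum(rr^2) / Nr,
    sum(rr^2) / Nr^2,
    Nr / np,
    sum((r - mu_r)^2 * p),
    sum(p / r^2),
    sum(i^2 / r^2 * p),
    sum(p / (i^2 * r^2)))
}

#' Gray level size zone matrix features
#'
#' The 16 GLSZM features from 26-connected constant-level zones.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(roi) {
  lev <- roi_levels(roi)
  np <- sum(lev > 0)
  if (np < 1) return(flagged_na(glszm_feature_names()))
  P <- cpp_glszm(lev, dim(lev), roi$n_levels)
  Nz <- sum(P)
  i <- row(P); s <- col(P)
  p <- P / Nz
  gi <- rowSums(P); sz <- colSums(P)
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  eps <- the_eps
  setNames(c(
    sum(gi^2) / Nz,
    sum(gi^2) / Nz^2,
    sum((i - mu_i)^2 * p),
    sum(i^2 * p),
    sum(s^2 * p),
    sum(i^2 * s^2 * p),
    sum(s^2 / i^2 * p),
    sum(p / i^2),
    sum(sz^2) / Nz,
    sum(sz^2) / Nz^2,
    sum(p / s^2),
    sum(i^2 / s^2 * p),
    sum(p / (i^2 * s^2)),
    -sum(p * log2(p + eps)),
    Nz / np,
    sum((s - mu_s)^2 * p)), glszm_feature_names())
}

glszm_feature_names <- function() c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance")

#' Gray level dependence matrix features
#'
#' The 14 GLDM features; the dependence of a voxel is one plus the number of
#' its 26-neighbours inside the mask with the same gray level (alpha = 0).
#'
#' @inheritParams glcm_features
#' @param alpha gray-level difference tolerance for dependence counting.
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(roi, alpha = 0L) {
  lev <- roi_levels(roi)
  np <- sum(lev > 0)
  if (np < 1) return(flagged_na(gldm_feature_names()))
  P <- cpp_gldm(lev, dim(lev), roi$n_levels, as.integer(alpha))
  Nz <- sum(P)
  i <- row(P); j <- col(P)   # column k means dependence size k (= count + 1)
  p <- P / Nz
  gi <- rowSums(P); dj <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  eps <- the_eps
  setNames(c(
    -sum(p * log2(p + eps)),
    sum(dj^2) / Nz,
    sum(dj^2) / Nz^2,
    sum((j - mu_j)^2 * p),
    sum(gi^2) / Nz,
    sum((i - mu_i)^2 * p),
    sum(i^2 * p),
    sum(j^2 * p),
    sum(i^2 * j^2 * p),
    sum(j^2 / i^2 * p),
    sum(p / i^2),
    sum(p / j^2),
    sum(i^2 / j^2 * p),
    sum(p / (i^2 * j^2))), gldm_feature_names())
}

gldm_feature_names <- function() c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis")

#' Neighbouring gray tone difference matrix features
#'
#' The 5 NGTDM features (coarseness, contrast, busyness, complexity,
#' strength) from per-level counts and absolute differences to the mean of
#' the masked 26-neighbourhood.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(roi) {
  lev <- roi_levels(roi)
  if (sum(lev > 0) < 1) return(flagged_na(ngtdm_feature_names()))
  M <- cpp_ngtdm(lev, dim(lev), roi$n_levels)
  n_i <- M[, 1]; s_i <- M[, 2]
  Nv <- sum(n_i)
  if (Nv == 0) return(flagged_na(ngtdm_feature_names()))
  p <- n_i / Nv
  act <- which(p > 0)
  ngp <- length(act)
  lv <- seq_along(p)
  coarse <- if (sum(p * s_i) > 0) 1 / sum(p * s_i) else 1e6
  if (ngp > 1) {
    pij <- outer(p[act], p[act])
    dij2 <- outer(lv[act], lv[act], function(a, b) (a - b)^2)
    contrast <- sum(pij * dij2) / (ngp * (ngp - 1)) * sum(s_i) / Nv
    ipi <- lv[act] * p[act]
    busy_den <- sum(abs(outer(ipi, ipi, "-")))
    busy <- if (busy_den > 0) sum(p * s_i) / busy_den else 0
    psi <- p[act] * s_i[act]
    complexity <- sum(abs(outer(lv[act], lv[act], "-")) *
                        outer(psi, psi, "+") / outer(p[act], p[act], "+")) / Nv
    strength <- if (sum(s_i) > 0) sum(outer(p[act], p[act], "+") * dij2) / sum(s_i) else 0
  } else {
    contrast <- 0; busy <- 0; complexity <- 0; strength <- 0
  }
  setNames(c(busy, coarse, complexity, contrast, strength), ngtdm_feature_names())
}

ngtdm_feature_names <- function() c(
  "Busyness", "Coarseness", "Complexity", "Contrast", "Strength")

flagged_na <- function(nms) {
  out <- setNames(rep(NA_real_, length(nms)), nms)
  attr(out, "flagged") <- TRUE
  out
}
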