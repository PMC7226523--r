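test_that("GLCM features match hand enumeration on a 2x2 slab", {
  # levels (x,y): (1,1)=1 (2,1)=1 (1,2)=1 (2,2)=2, single slice.
  # In-plane direction counts: (1,0,0) and (0,1,0): {1-1, 1-2};
  # (1,1,0): {1-2}; (1,-1,0): {1-1}; out-of-plane directions empty.
  lev <- array(0L, c(2, 2, 2))
  lev[1, 1, 1] <- 1L; lev[2, 1, 1] <- 1L; lev[1, 2, 1] <- 1L; lev[2, 2, 1] <- 2L
  g <- glcm_features(as_roi(lev))
  expect_equal(unname(g["Contrast"]), (0.5 + 0.5 + 1 + 0) / 4)
  expect_equal(unname(g["MaximumProbability"]), (0.5 + 0.5 + 0.5 + 1) / 4)
  expect_equal(unname(g["JointAverage"]), (1.25 + 1.25 + 1.5 + 1) / 4)
})

test_that("degenerate single-level ROI takes the documented sentinels", {
  g <- glcm_features(as_roi(array(1L, c(3, 3, 3))))
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["Correlation"]), 1)   # sentinel
  expect_equal(unname(g["MCC"]), 1)           # sentinel
  expect_equal(unname(g["JointEntropy"]), 0, tolerance = 1e-10)
  expect_equal(unname(g["JointEnergy"]), 1)
})

test_that("co-occurrence, run and zone matrices match brute-force enumeration", {
  set.seed(7)
  for (i in 1:12) {
    lev <- random_roi(d = sample(3:5, 3, replace = TRUE), ng = sample(2:4, 1))
    ng <- max(lev)
    glcm_cpp <- radprog:::cpp_glcm(lev, dim(lev), ng)
    expect_equal(as.numeric(glcm_cpp), as.numeric(bf_glcm(lev, ng)))
    rl_cpp <- radprog:::cpp_glrlm(lev, dim(lev), ng)
    rl_bf <- bf_glrlm(lev, ng)
    expect_equal(as.numeric(rl_cpp[, seq_len(dim(rl_bf)[2]), ]),
                 as.numeric(rl_bf))
    if (dim(rl_cpp)[2] > dim(rl_bf)[2])
      expect_true(all(rl_cpp[, (dim(rl_bf)[2] + 1):dim(rl_cpp)[2], ] == 0))
    sz_cpp <- radprog:::cpp_glszm(lev, dim(lev), ng)
    sz_bf <- bf_glszm(lev, ng)
    expect_equal(as.numeric(sz_cpp[, seq_len(ncol(sz_bf))]), as.numeric(sz_bf))
  }
})

test_that("runs and zones of a constant 3x3x3 ROI are enumerable by hand", {
  lev <- array(1L, c(3, 3, 3))
  rl <- radprog:::cpp_glrlm(lev, dim(lev), 1L)
  expect_equal(rl[1, 3, 1], 9)         # axis direction: 9 runs of length 3
  expect_equal(sum(rl[1, , 1]), 9)
  expect_equal(rl[1, , 4], c(6, 6, 3)) # in-plane diagonal: 1,2,3,2,1 per slab
  sz <- glszm_features(as_roi(lev))
  expect_equal(unname(sz["SizeZoneNonUniformity"]), 1)  # a single zone
  expect_equal(unname(sz["ZonePercentage"]), 1 / 27)
})

test_that("NGTDM features of a 3x3 checkerboard slab match hand sums", {
  lev <- array(0L, c(3, 3, 2))
  lev[, , 1] <- matrix(c(1, 2, 1, 2, 1, 2, 1, 2, 1), 3, 3)
  f <- ngtdm_features(as_roi(lev))
  # n1 = 5, s1 = 4*(2/3) + 1/2; n2 = 4, s2 = 4*(3/5)
  s1 <- 19 / 6; s2 <- 12 / 5; p1 <- 5 / 9; p2 <- 4 / 9
  expect_equal(unname(f["Coarseness"]), 1 / (p1 * s1 + p2 * s2))
  expect_equal(unname(f["Contrast"]), (2 * p1 * p2 / 2) * (s1 + s2) / 9)
  expect_equal(unname(f["Busyness"]), (p1 * s1 + p2 * s2) / (2 * abs(p1 - 2 * p2)))
  expect_equal(unname(f["Strength"]), 2 * (p1 + p2) / (s1 + s2))
})

test_that("zone-size emphasis ordering holds on a striped image", {
  lev <- array(0L, c(4, 4, 2))
  lev[, , 1] <- matrix(rep(c(1L, 2L), each = 4), 4, 4)  # two stripes of 8
  f <- glszm_features(as_roi(lev))
  expect_gt(f["LargeAreaEmphasis"], f["SmallAreaEmphasis"])
  g <- gldm_features(as_roi(lev))
  expect_gt(g["LargeDependenceEmphasis"], g["SmallDependenceEmphasis"])
})

test_that("first-order statistics match hand arithmetic", {
  v <- array(0, c(4, 1, 2)); v[, 1, 1] <- c(1, 2, 3, 4)
  m <- array(0L, c(4, 1, 2)); m[, 1, 1] <- 1L
  f <- firstorder_features(v, m, bin_width = 1, spacing_mm = c(1, 1, 1))
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["RootMeanSquared"]), sqrt(7.5))
  expect_equal(unname(f["Energy"]), 30)
  expect_equal(unname(f["Variance"]), 1.25)
  expect_equal(unname(f["Range"]), 3)
  # constant ROI degeneracy
  fc <- firstorder_features(array(3, c(3, 3, 3)), array(1L, c(3, 3, 3)), 25)
  expect_equal(unname(fc[c("Variance", "Entropy", "Skewness", "Kurtosis")]),
               c(0, 0, 0, 0))
  expect_equal(unname(fc["Uniformity"]), 1)
})

test_that("shape features of a digital ball approach the analytic solid", {
  b <- digital_ball(9)
  sf <- shape_features(b, c(2, 2, 2))
  r_mm <- 18
  expect_equal(unname(sf["Sphericity"]), 1, tolerance = 0.05)
  expect_equal(unname(sf["MeshVolume"]), 4 / 3 * pi * r_mm^3, tolerance = 0.05)
  expect_equal(unname(sf["Maximum3DDiameter"]), 2 * r_mm, tolerance = 0.08)
  expect_equal(unname(sf["Elongation"]), 1, tolerance = 0.02)
  expect_equal(unname(sf["Flatness"]), 1, tolerance = 0.02)
  expect_equal(unname(sf["MajorAxisLength"]), 4 * sqrt(r_mm^2 / 5),
               tolerance = 0.05)  # eigenvalue r^2/5 for a solid ball
})

test_that("direction-averaged texture features are invariant to 90-degree rotation", {
  set.seed(11)
  lev <- random_roi(c(6, 6, 6), ng = 4)
  rot <- aperm(lev, c(2, 1, 3))[rev(seq_len(6)), , ]  # 90 deg about axis 3
  for (fn in list(glcm_features, glrlm_features, glszm_features,
                  gldm_features, ngtdm_features)) {
    a <- fn(as_roi(lev)); b <- fn(as_roi(rot))
    expect_equal(a, b, tolerance = 1e-10)
  }
})
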