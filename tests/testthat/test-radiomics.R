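test_that("quantization bins equal-width between frame min and max", {
  ramp <- matrix(rep(0:255, each = 8), nrow = 8)
  q <- quantize_gray(ramp, 32)
  expect_equal(sort(unique(as.vector(q))), 1:32)
  expect_equal(unname(table(q)), rep(64, 32), ignore_attr = TRUE)
  expect_true(all(quantize_gray(matrix(7, 10, 10), 32) == 1))
  expect_error(quantize_gray(ramp, 1), "n_levels")
})

test_that("intensity features match closed forms on simple frames", {
  const <- matrix(100, 20, 20)
  f <- intensity_features(const)
  expect_equal(length(f), 16)
  expect_equal(unname(f[c("mean", "variance", "entropy", "skewness")]),
               c(100, 0, 0, 0))
  expect_equal(unname(f["uniformity"]), 1)

  two <- matrix(c(rep(0, 50), rep(200, 50)), 10, 10)
  f2 <- intensity_features(two)
  expect_equal(unname(f2["entropy"]), 1)       # two equal bins, 1 bit
  expect_equal(unname(f2["uniformity"]), 0.5)
  expect_equal(unname(f2["mean"]), 100)
  expect_equal(unname(f2["rms"]), sqrt(mean(two^2)))
  expect_equal(unname(f2["energy"]), sum(two^2))
})

test_that("intensity mean and variance are shift/scale equivariant", {
  set.seed(5)
  for (i in 1:20) {
    x <- matrix(stats::rnorm(400, 100, 20), 20, 20)
    a <- stats::runif(1, 0.5, 3); b <- stats::runif(1, -50, 50)
    f1 <- intensity_features(x)
    f2 <- intensity_features(a * x + b)
    expect_equal(unname(f2["mean"]), a * f1[["mean"]] + b)
    expect_equal(unname(f2["variance"]), a^2 * f1[["variance"]])
  }
})

test_that("texture features hit their degenerate and hand-computed values", {
  const <- matrix(5, 24, 24)
  tx <- texture_features(const)
  expect_equal(length(tx), 54)
  expect_equal(unname(tx["glcm_contrast"]), 0)
  expect_equal(unname(tx["glcm_correlation"]), 0)   # documented degenerate
  expect_equal(unname(tx["glcm_inverse_difference"]), 1)
  expect_equal(unname(tx["glcm_inverse_difference_moment"]), 1)
  expect_equal(unname(tx["glcm_joint_energy"]), 1)

  # checkerboard of two levels: 0-degree co-occurrence has only (1,2)/(2,1)
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  q <- quantize_gray(cb, 2)
  p0 <- dsavm:::glcm_matrix(q, 0, 1, 2)
  expect_equal(p0[1, 1] + p0[2, 2], 0)
  g0 <- dsavm:::glcm_features_one(p0, 2)
  expect_equal(unname(g0["contrast"]), 1)

  # run lengths of a tiny matrix, horizontal direction: rows (1,1,2) twice
  m <- matrix(c(1, 1, 1, 1, 2, 2), nrow = 2)
  rl <- dsavm:::glrlm_matrix(m, "h", 2)
  expect_equal(rl[1, 2], 2)  # two runs of level 1, length 2
  expect_equal(rl[2, 1], 2)  # two runs of level 2, length 1

  # size zones of a tiny matrix: one 4-zone of 1s, one 2-zone of 2s
  z <- dsavm:::label_zones(m)
  expect_equal(sort(z$size), c(2, 4))
  sz <- glszm_features(m, 2)
  expect_equal(length(sz), 16)
  expect_equal(unname(sz["zp"]), 2 / 6)  # 2 zones over 6 pixels
})

test_that("wavelet decomposition yields 8 subbands and reconstructs", {
  set.seed(9)
  x <- matrix(stats::rnorm(32 * 32, 100, 25), 32, 32)
  sb <- wavelet_subbands(x)
  expect_equal(names(sb), c("LL1", "LH1", "HL1", "HH1",
                            "LL2", "LH2", "HL2", "HH2"))
  # level-1 perfect reconstruction
  l1 <- dsavm:::haar_dwt2(x)
  back <- dsavm:::haar_idwt2(l1, 32, 32)
  expect_lt(max(abs(back - x)), 1e-8)
  # odd dimensions survive the symmetric padding round trip
  xo <- x[1:31, 1:29]
  lo <- dsavm:::haar_dwt2(xo)
  expect_lt(max(abs(dsavm:::haar_idwt2(lo, 31, 29) - xo)), 1e-8)
  # constant frame: all detail subbands identically zero
  sbc <- wavelet_subbands(matrix(3, 16, 16))
  for (nm in setdiff(names(sbc), c("LL1", "LL2"))) {
    expect_true(all(abs(sbc[[nm]]) < 1e-12))
  }
  expect_error(wavelet_subbands(matrix(0, 8, 8)), "16x16")
})

test_that("feature-count contracts hold at every level", {
  set.seed(2)
  x <- matrix(stats::rnorm(48 * 48, 120, 30), 48, 48)
  expect_equal(length(intensity_features(x)), 16)
  expect_equal(length(texture_features(x)), 54)
  expect_equal(length(wavelet_subbands(x)), 8)
  wf <- wavelet_features(x)
  expect_equal(length(wf), 280)
  expect_equal(sum(startsWith(names(wf), "LL1_")), 35)  # 280 / 8 per subband
  fr <- frame_radiomics(x)
  expect_equal(length(fr), 350)
  expect_true(all(is.finite(fr)))
})

test_that("the per-case vector is frame-major, deterministic, length 1750", {
  case <- phantom_fixture("AVM", seed = 17)
  v1 <- case_radiomics_vector(case$frames, c(2, 8, 8, 20, 28))
  v2 <- case_radiomics_vector(case$frames, c(2, 8, 8, 20, 28))
  expect_identical(v1, v2)
  expect_equal(length(v1), 1750)
  # duplicated key frames give identical 350-blocks
  b2 <- v1[startsWith(names(v1), "f2_")]
  b3 <- v1[startsWith(names(v1), "f3_")]
  expect_equal(unname(b2), unname(b3))
  expect_equal(length(b2), 350)
  expect_error(case_radiomics_vector(case$frames, c(0, 1, 2, 3, 99)),
               "out of range")
  expect_error(case_radiomics_vector(case$frames, c(0, 1, 2)), "5 key frames")
})
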