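# The 16 spatial-variability operators against hand values and the
# brute-force oracles.

test_that("statistical features match hand-computed values", {
  f <- statistical_features(c(1, 2, 3, 4))
  expect_equal(f[["A"]], 2.5)
  expect_equal(f[["VAR"]], 1.25)
  expect_equal(f[["INE"]], 3)
  expect_equal(f[["ACOR"]], 0.25)
  expect_equal(f[["KUR"]], -1.36)
  expect_equal(statistical_features(c(1, 2, 2, 3))[["SKE"]], 0)
  const <- statistical_features(rep(2, 10))
  expect_equal(unname(const[c("VAR", "IQR", "COV", "SKE", "KUR", "ACOR")]),
               rep(0, 6))
})

test_that("quantize performs min-max binning with stable endpoints", {
  expect_equal(quantize(rep(3.3, 16), 16L), rep(0L, 16))
  expect_equal(sort(quantize(seq(0, 1, length.out = 16), 16L)), 0:15)
  x <- rnorm(100)
  q <- quantize(x, 16L)
  expect_equal(q[which.min(x)], 0L)
  expect_equal(q[which.max(x)], 15L)
})

test_that("profile_to_square stacks identical rows", {
  m <- profile_to_square(c(5, 1, 4, 2, 3))
  expect_equal(dim(m), c(5L, 5L))
  for (r in 2:5) expect_equal(m[r, ], m[1, ])
  expect_true(all(apply(m, 2, function(col) length(unique(col)) == 1)))
})

test_that("stacked-square GLCM equals adjacent-pair co-occurrence of the profile", {
  set.seed(11)
  x <- rnorm(10)
  q1 <- quantize(x, 8L)
  g_sq <- glcm(matrix(rep(q1, each = 10), nrow = 10), levels = 8L)
  # direct enumeration over the 1D adjacent pairs
  counts <- matrix(0, 8, 8)
  for (i in 1:9) {
    counts[q1[i] + 1, q1[i + 1] + 1] <- counts[q1[i] + 1, q1[i + 1] + 1] + 1
    counts[q1[i + 1] + 1, q1[i] + 1] <- counts[q1[i + 1] + 1, q1[i] + 1] + 1
  }
  expect_equal(g_sq$p, counts / sum(counts))
})

test_that("glcm handles degenerate and checkerboard grids", {
  g_const <- glcm(matrix(0L, 4, 4), levels = 4L)
  expect_equal(g_const$p[1, 1], 1)
  expect_equal(sum(g_const$p), 1)
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2L)
  g_cb <- glcm(cb, levels = 2L)
  expect_equal(g_cb$p[1, 2], 0.5)
  expect_equal(g_cb$p[2, 1], 0.5)
  expect_equal(g_cb$p[1, 1], 0)
  feats <- glcm_features(g_cb)
  expect_equal(feats[["CON"]], 1)
  expect_equal(feats[["ASM"]], 0.5)
  expect_equal(feats[["HOM"]], 0.5)
  expect_equal(feats[["INEM"]], 1)
  expect_error(glcm(matrix(NA_integer_, 3, 3)), "no valid pairs")
})

test_that("structural features hit the degenerate and uniform anchors", {
  s_const <- structural_features(rep(1.5, 16))
  expect_equal(s_const[["CON"]], 0)
  expect_equal(s_const[["ASM"]], 1)
  expect_equal(s_const[["HOM"]], 1)
  expect_equal(s_const[["TENT"]], 0, tolerance = 1e-6)
  expect_equal(s_const[["SENT"]], 0, tolerance = 1e-6)
  expect_equal(s_const[["LENT"]], 0)
  # a ramp over 16 values occupies each of 16 levels once: SENT = 4 bits
  s_ramp <- structural_features(seq(0, 1, length.out = 16))
  expect_equal(s_ramp[["SENT"]], 4, tolerance = 1e-6)
})

test_that("all 16 operators match the brute-force oracle on random supports", {
  set.seed(101)
  for (k in 1:10) {
    x <- rnorm(12)
    expect_equal(spatial_features(x), oracle_all16(x), tolerance = 1e-9)
    m <- matrix(rnorm(144), 12, 12)
    expect_equal(spatial_features(m), oracle_all16(m), tolerance = 1e-9)
  }
  # masked 2D patch (NAs outside a disk)
  m <- matrix(rnorm(144), 12, 12)
  m[(row(m) - 6)^2 + (col(m) - 6)^2 > 25] <- NA
  expect_equal(spatial_features(m), oracle_all16(m), tolerance = 1e-9)
})

test_that("GLCM features are shift-invariant and SENT is permutation-invariant", {
  set.seed(42)
  x <- rnorm(30)
  f1 <- structural_features(x)
  f2 <- structural_features(x + 17.3)
  expect_equal(f1[c("SENT", "CON", "ASM", "TENT", "HOM", "INEM")],
               f2[c("SENT", "CON", "ASM", "TENT", "HOM", "INEM")],
               tolerance = 1e-9)
  xs <- sample(x)
  fs <- structural_features(xs)
  expect_equal(fs[["SENT"]], f1[["SENT"]], tolerance = 1e-9)  # histogram only
  expect_false(isTRUE(all.equal(fs[["CON"]], f1[["CON"]])))
  expect_false(isTRUE(all.equal(fs[["TENT"]], f1[["TENT"]])))
  expect_false(isTRUE(all.equal(fs[["INEM"]], f1[["INEM"]])))
})

test_that("feature table has 624 deterministic columns plus targets", {
  ds <- tiny_dataset()
  ft <- build_feature_table(ds)
  expect_equal(length(feature_names()), 16 * 13 * 3)
  expect_true(all(feature_names() %in% colnames(ft)))
  expect_equal(nrow(ft), length(ds$samples))
  expect_false(anyNA(ft))
  # determinism: rebuilding the same dataset gives an identical table
  ds2 <- build_dataset(replicates = 1L, seed = 7L, noise_scale = 0,
                       abnormal_frac = 0)
  ft2 <- build_feature_table(ds2)
  expect_identical(ft, ft2)
})
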