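# Synthetic-data generator: geometry, simulators, temperature, datasets.

test_that("leaf geometry satisfies its invariants", {
  # circle: symmetric, falls back with a warning, axis spans the diameter
  expect_warning(
    geo_c <- make_leaf_geometry(a = 30, b = 30, boundary_noise = 0),
    "isotropic")
  len <- coldpheno:::vein_axis_length(geo_c)
  expect_gte(len, 58); expect_lte(len, 60)
  # rotated ellipse: direction recovered within 2 degrees
  geo_e <- make_leaf_geometry(a = 60, b = 30, rotation_deg = 30,
                              boundary_noise = 0, shape = c(160L, 160L))
  ang <- atan2(geo_e$vein_dir[1], geo_e$vein_dir[2]) * 180 / pi
  expect_lt(abs(ang - 30), 2)
  # widest chord endpoints always inside the mask
  for (seed in 1:5) {
    g <- make_leaf_geometry(rotation_deg = runif(1, 0, 180), seed = seed)
    expect_true(all(g$mask[g$widest_chord + 1]))
    expect_true(g$mask[round(g$vein_point[1]) + 1, round(g$vein_point[2]) + 1])
  }
  expect_error(make_leaf_geometry(a = 4, b = 4), "semi-axes")
})

test_that("fluorescence simulation round-trips targets at zero noise", {
  geo <- make_leaf_geometry(seed = 2)
  m <- geo$mask
  const <- function(v) matrix(v, 64, 64)
  targets <- list(yii = const(0.5), ynpq = const(0.3), yno = const(0.2),
                  qp = const(0.7), fvfm = const(0.8))
  fr <- simulate_fluorescence(geo, targets, noise_sd = 0, seed = 1)
  maps <- fluorescence_maps(clean_frames(fr))
  expect_equal(max(abs(maps[["Fv/Fm"]]$values[m] - 0.8)), 0, tolerance = 1e-9)
  expect_equal(max(abs(maps[["Y(II)"]]$values[m] - 0.5)), 0, tolerance = 1e-9)
  expect_equal(max(abs(maps[["qP"]]$values[m] - 0.7)), 0, tolerance = 1e-9)
  expect_equal(max(abs(maps[["Y(NO)"]]$values[m] - 0.2)), 0, tolerance = 1e-9)
  # NPQ = 0 targets (ynpq = 0) give fm' = fm inside the mask
  t0 <- list(yii = const(0.5), ynpq = const(0), yno = const(0.5),
             qp = const(0.7))
  fr0 <- simulate_fluorescence(geo, t0, seed = 1)
  expect_equal(fr0$fm_p[m], fr0$fm[m], tolerance = 1e-12)
  # inconsistent yields rejected
  bad <- list(yii = const(0.5), ynpq = const(0.4), yno = const(0.2),
              qp = const(0.7))
  expect_error(simulate_fluorescence(geo, bad), "!= 1")
})

test_that("a qP gradient along the vein is recovered as a monotone profile", {
  geo <- make_leaf_geometry(rotation_deg = 40, boundary_noise = 0, seed = 4)
  rows <- matrix(0:63, 64, 64); cols <- matrix(0:63, 64, 64, byrow = TRUE)
  u <- (rows - geo$vein_point[1]) * geo$vein_dir[1] +
       (cols - geo$vein_point[2]) * geo$vein_dir[2]
  u <- u / max(abs(u[geo$mask]))
  qp <- 0.55 + 0.2 * u                      # increases along the vein
  targets <- list(yii = matrix(0.3, 64, 64), ynpq = matrix(0.35, 64, 64),
                  yno = matrix(0.35, 64, 64), qp = qp)
  fr <- simulate_fluorescence(geo, targets, seed = 1)
  qp_map <- fluorescence_maps(clean_frames(fr))[["qP"]]
  prof <- parallel_transect(qp_map, geo)
  expect_true(all(diff(prof$values) >= 0))
  expect_gt(prof$values[length(prof$values)], prof$values[1])
})

test_that("band simulation round-trips index targets at zero noise", {
  geo <- make_leaf_geometry(seed = 3)
  m <- geo$mask
  const <- function(v) matrix(v, 64, 64)
  # NDVI = 0 everywhere -> nir equals red inside the mask
  b0 <- simulate_bands(geo, list(ndvi = const(0), ndving = const(0.4),
                                 ndvinb = const(0.5)))
  expect_equal(b0$nir[m], b0$red[m], tolerance = 1e-12)
  # uniform NDVI 0.6 round-trips
  b1 <- simulate_bands(geo, list(ndvi = const(0.6), ndving = const(0.4),
                                 ndvinb = const(0.5)))
  ndvi <- spectral_index_maps(b1)[["NDVI"]]
  expect_equal(max(abs(ndvi$values[m] - 0.6)), 0, tolerance = 1e-9)
  # checkerboard NDVIgb: encode via ndvinb = 0 and ndving = -target
  cb <- 0.2 * outer(1:64, 1:64, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  b2 <- simulate_bands(geo, list(ndvi = const(0.5), ndving = -cb,
                                 ndvinb = const(0)))
  gb <- spectral_index_maps(b2)[["NDVIgb"]]
  expect_equal(max(abs(gb$values[m] - cb[m])), 0, tolerance = 1e-9)
  expect_error(simulate_bands(geo, list(ndvi = const(1.2), ndving = const(0),
                                        ndvinb = const(0))), "outside")
})

test_that("temperature profiles honor the diurnal anchors", {
  d <- factorial_designs()
  ck <- make_temperature_profile(d$CKD2)
  expect_equal(length(ck$hourly_c), 144)
  for (day in 1:6) {
    block <- ck$hourly_c[(24 * (day - 1) + 1):(24 * day)]
    expect_equal(max(block), 25, tolerance = 0.01)
    expect_equal(min(block), 15, tolerance = 0.01)
  }
  # equal amplitudes -> constant hourly offset (15 degC for T4 vs CK)
  t4 <- make_temperature_profile(d$T4D2)
  expect_equal(unique(round(ck$hourly_c - t4$hourly_c, 9)), 15)
  expect_equal(length(make_temperature_profile(d$T1D1)$hourly_c), 72)
  expect_error(treatment_design(10, 15, 3, "bad"), "exceed")
})

test_that("build_dataset produces the factorial with exact round-trips", {
  ds <- build_dataset(replicates = 2L, seed = 11L, noise_scale = 0,
                      abnormal_frac = 0, rasters = FALSE)
  expect_equal(nrow(ds$ground_truth), 5 * 3 * 2)
  # CK samples have RNAT 0, hence CDRI = PPPI
  ck_rows <- ds$ground_truth$temp == "CK"
  expect_true(all(ds$ground_truth$RNAT[ck_rows] == 0))
  expect_equal(ds$ground_truth$CDRI[ck_rows], ds$ground_truth$PPPI[ck_rows])
  # physio round-trip at zero noise: REC and Chl to 1e-9, P_max within 1 %
  for (sid in names(ds$samples)[c(1, 18, 30)]) {
    smp <- ds$samples[[sid]]
    gtr <- ds$ground_truth[ds$ground_truth$sample_id == sid, ]
    expect_equal(rec(smp$physio_raw$C1, smp$physio_raw$C2), gtr$REC,
                 tolerance = 1e-9)
    expect_equal(chlorophyll(smp$physio_raw$A649, smp$physio_raw$A665),
                 gtr$`Chl_a+b`, tolerance = 1e-9)
    fit <- fit_light_response(smp$physio_raw$light_I, smp$physio_raw$light_Pn)
    expect_lt(abs(fit$p_max - gtr$P_max) / gtr$P_max, 0.01)
  }
})

test_that("identical seed and config give identical datasets", {
  d1 <- build_dataset(replicates = 1L, seed = 5L)
  d2 <- build_dataset(replicates = 1L, seed = 5L)
  expect_identical(d1$ground_truth, d2$ground_truth)
  expect_identical(d1$samples[[4]]$frames$fs, d2$samples[[4]]$frames$fs)
  expect_identical(d1$samples[[9]]$bands$nir, d2$samples[[9]]$bands$nir)
})

test_that("mean REC is nondecreasing in stress dose (Spearman >= 0.9)", {
  # expectation check on the treatment means themselves
  means <- coldpheno:::treatment_means()
  trt <- means[means$temp != "CK", ]
  delta <- c(T1 = 6, T2 = 9, T3 = 12, T4 = 15)[trt$temp]
  dose <- delta * c(3, 6, 9)[trt$duration_index]
  expect_gte(cor(dose, trt$rec, method = "spearman"), 0.9)
  # and on sampled ground truth at n = 50 replicates per cell
  ds <- build_dataset(replicates = 50L, seed = 23L, rasters = FALSE)
  gt <- ds$ground_truth[ds$ground_truth$temp != "CK", ]
  agg <- aggregate(gt$REC, list(gt$treatment), mean)
  dd <- c(T1 = 6, T2 = 9, T3 = 12, T4 = 15)[sub("D[0-9]$", "", agg$Group.1)] *
    c(3, 6, 9)[as.integer(sub("^T[0-9]D", "", agg$Group.1))]
  expect_gte(cor(dd, agg$x, method = "spearman"), 0.9)
})
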