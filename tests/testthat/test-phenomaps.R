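# Frame cleaning, fluorescence parameter maps, band means, ND indices.

make_frames <- function(fo = 200, fm = 1000, fo_p = 180, fm_p = 800, fs = 400,
                        shape = c(16L, 16L)) {
  msk <- matrix(TRUE, shape[1], shape[2])
  geo <- list(mask = msk)
  const <- function(v) matrix(v, shape[1], shape[2])
  fluor_frame_set(const(fo), const(fm), const(fo_p), const(fm_p), const(fs), geo)
}

test_that("clean_frames drops only invariant-violating pixels", {
  fr <- make_frames()
  cl <- clean_frames(fr)
  expect_equal(cl$geometry$mask, fr$geometry$mask)
  # one pixel with fs > fm' is excluded, all others kept
  fr2 <- make_frames()
  fr2$fs[3, 5] <- fr2$fm_p[3, 5] + 1
  cl2 <- clean_frames(fr2)
  expect_false(cl2$geometry$mask[3, 5])
  expect_equal(sum(cl2$geometry$mask), 16 * 16 - 1)
  # 60 % corruption -> error naming the invariant
  fr3 <- make_frames()
  bad <- sample(256, 154)
  fr3$fs[bad] <- fr3$fm_p[bad] * 2
  expect_error(clean_frames(fr3), "Fm' < Fs", fixed = TRUE)
})

test_that("fluorescence maps follow the quenching formulas", {
  fr <- make_frames(fo = 0.2 * 1000, fm = 1000)
  maps <- fluorescence_maps(clean_frames(fr))
  expect_equal(maps[["Fv/Fm"]]$values[1, 1], 0.8)
  # Fm' = Fm -> NPQ = 0 and qN = 0
  fr2 <- make_frames(fm_p = 1000, fo_p = 200)
  maps2 <- fluorescence_maps(clean_frames(fr2))
  expect_equal(maps2[["NPQ"]]$values[2, 2], 0)
  expect_equal(maps2[["qN"]]$values[2, 2], 0)
  # energy partition sums to 1 exactly on random physical frames
  set.seed(5)
  msk <- matrix(TRUE, 8, 8)
  fm <- matrix(runif(64, 800, 1200), 8, 8)
  fm_p <- fm * matrix(runif(64, 0.5, 1), 8, 8)
  fs <- fm_p * matrix(runif(64, 0.2, 0.9), 8, 8)
  fo <- fm * 0.2; fo_p <- pmin(fo, fs * 0.9)
  fr3 <- fluor_frame_set(fo, fm, fo_p, fm_p, fs, list(mask = msk))
  m3 <- fluorescence_maps(clean_frames(fr3))
  total <- m3[["Y(II)"]]$values + m3[["Y(NPQ)"]]$values + m3[["Y(NO)"]]$values
  expect_equal(max(abs(total - 1)), 0, tolerance = 1e-12)
})

test_that("fluorescence maps are invariant to a common frame rescaling", {
  fr <- make_frames()
  maps1 <- fluorescence_maps(clean_frames(fr))
  fr2 <- fr
  for (nm in c("fo", "fm", "fo_p", "fm_p", "fs")) fr2[[nm]] <- fr2[[nm]] * 7.3
  maps2 <- fluorescence_maps(clean_frames(fr2))
  for (nm in names(maps1))
    expect_equal(maps1[[nm]]$values, maps2[[nm]]$values, tolerance = 1e-12)
})

test_that("band_mean averages native bands whose centers fall in the window", {
  wl <- seq(375.88, 1039.19, by = 2.6)
  cube <- array(0.4, dim = c(4, 4, length(wl)))
  bm <- band_mean(cube, c(780, 790), wavelengths_nm = wl)
  expect_true(all(bm == 0.4))
  expect_true(attr(bm, "n_bands") %in% 4:5)
  # reflectance linear in nm: mean == value at window midpoint +- half spacing
  lin <- array(rep(wl / 1000, each = 16), dim = c(4, 4, length(wl)))
  bl <- band_mean(lin, c(545, 555), wavelengths_nm = wl)
  expect_lt(abs(bl[1, 1] - 550 / 1000), 2.6 / 2 / 1000)
  expect_error(band_mean(cube, c(2000, 2010), wavelengths_nm = wl), "no band")
})

test_that("nd_index computes (a-b)/(a+b) with mask handling", {
  a <- matrix(0.5, 4, 4); b <- matrix(0.5, 4, 4)
  expect_true(all(nd_index(a, b)$values == 0))
  expect_true(all(nd_index(a, matrix(0, 4, 4))$values == 1))
  expect_equal(nd_index(matrix(0.5, 1, 1), matrix(0.1, 1, 1))$values[1, 1],
               0.6667, tolerance = 1e-4)
  expect_error(nd_index(a, matrix(1, 2, 2)), "shape")
  # a + b = 0 pixels drop out of the mask
  z <- nd_index(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_false(any(z$mask))
})

test_that("the five spectral indices are antisymmetric", {
  set.seed(9)
  a <- matrix(runif(64, 0.1, 0.9), 8, 8)
  b <- matrix(runif(64, 0.1, 0.9), 8, 8)
  expect_equal(nd_index(a, b)$values, -nd_index(b, a)$values)
})
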