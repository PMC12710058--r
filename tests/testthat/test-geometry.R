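# Leaf-mask geometry: vein axis, transects, inscribed region.

make_ellipse_mask <- function(a, b, theta_deg = 0, shape = c(128L, 128L)) {
  nr <- shape[1]; nc <- shape[2]
  ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  th <- theta_deg * pi / 180
  rows <- matrix(0:(nr - 1), nr, nc) - ctr[1]
  cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE) - ctr[2]
  u <- cols * cos(th) + rows * sin(th)
  v <- -cols * sin(th) + rows * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

angle_deg <- function(dir) atan2(dir[1], dir[2]) * 180 / pi

test_that("vein axis tracks the mask's principal elongation", {
  ax0 <- estimate_vein_axis(make_ellipse_mask(60, 30, 0))
  expect_lt(abs(angle_deg(ax0$vein_dir)), 2)
  ax90 <- estimate_vein_axis(make_ellipse_mask(60, 30, 90))
  expect_lt(abs(abs(angle_deg(ax90$vein_dir)) - 90), 2)
  # oracle: brute-force second-moment axis over mask pixels at 30 degrees
  msk <- make_ellipse_mask(60, 30, 30)
  ax30 <- estimate_vein_axis(msk)
  px <- which(msk, arr.ind = TRUE)
  cc <- cov(px)
  ev <- eigen(cc)$vectors[, 1]
  if (ev[1] < 0) ev <- -ev
  expect_lt(acos(abs(sum(ax30$vein_dir * ev))) * 180 / pi, 2)
  expect_lt(abs(angle_deg(ax30$vein_dir) - 30), 2)
  expect_warning(estimate_vein_axis(make_ellipse_mask(40, 40, 0)), "isotropic")
})

test_that("parallel transect samples the vein line inside the mask", {
  geo <- make_leaf_geometry(a = 30, b = 16, rotation_deg = 25,
                            boundary_noise = 0, shape = c(96L, 96L))
  uniform <- param_map("u", matrix(2.5, 96, 96), geo$mask)
  prof <- parallel_transect(uniform, geo)
  expect_true(all(prof$values == 2.5))
  expect_true(all(geo$mask[prof$pixel_coords + 1]))
  # ramp along the axis -> monotone profile
  rows <- matrix(0:95, 96, 96); cols <- matrix(0:95, 96, 96, byrow = TRUE)
  ramp <- rows * geo$vein_dir[1] + cols * geo$vein_dir[2]
  prof_r <- parallel_transect(param_map("r", ramp, geo$mask), geo)
  expect_true(all(diff(prof_r$values) > 0))
})

test_that("perpendicular transect crosses at the widest point", {
  geo <- make_leaf_geometry(a = 30, b = 16, rotation_deg = 0,
                            boundary_noise = 0, shape = c(96L, 96L))
  uniform <- param_map("u", matrix(1.0, 96, 96), geo$mask)
  perp <- perpendicular_transect(uniform, geo)
  # for an ellipse, the widest chord passes within 1 px of the centroid
  mid <- colMeans(perp$pixel_coords)
  expect_lt(sqrt(sum((mid - geo$vein_point)^2)), 1.5)
  # chord length ~= 2 b
  expect_lt(abs(length(perp$values) - 32), 2)
  # ramp perpendicular to the axis -> monotone
  rows <- matrix(0:95, 96, 96); cols <- matrix(0:95, 96, 96, byrow = TRUE)
  pdir <- c(-geo$vein_dir[2], geo$vein_dir[1])
  ramp <- rows * pdir[1] + cols * pdir[2]
  perp_r <- perpendicular_transect(param_map("r", ramp, geo$mask), geo)
  expect_true(all(diff(perp_r$values) > 0))
})

test_that("the two transect directions are orthogonal within 1 degree", {
  for (seed in 1:5) {
    geo <- make_leaf_geometry(rotation_deg = runif(1, 0, 180), seed = seed)
    uniform <- param_map("u", matrix(1, 64, 64), geo$mask)
    par_t <- parallel_transect(uniform, geo)
    per_t <- perpendicular_transect(uniform, geo)
    fit_dir <- function(pc) {
      # principal axis of the sampled pixels (averages rounding error)
      ev <- eigen(cov(pc))$vectors[, 1]
      ev / sqrt(sum(ev^2))
    }
    ang <- acos(abs(sum(fit_dir(par_t$pixel_coords) *
                          fit_dir(per_t$pixel_coords)))) * 180 / pi
    expect_gt(ang, 89)
  }
})

test_that("transect coordinates are independent of map values", {
  geo <- make_leaf_geometry(seed = 3)
  v <- matrix(rnorm(64 * 64), 64, 64)
  p1 <- parallel_transect(param_map("a", v, geo$mask), geo)
  p2 <- parallel_transect(param_map("a", 100 * v + 3, geo$mask), geo)
  expect_identical(p1$pixel_coords, p2$pixel_coords)
  expect_equal(p2$values, 100 * p1$values + 3)
})

test_that("region patch is the inscribed disk intersected with the mask", {
  msk <- make_ellipse_mask(20, 20, 0, shape = c(64L, 64L))
  geo <- list(mask = msk, vein_point = c(31.5, 31.5), vein_dir = c(0, 1))
  pm <- param_map("u", matrix(3, 64, 64), msk)
  patch <- region_patch(pm, geo)
  expect_lt(abs(patch$radius - 20), 1.01)
  vals <- patch$values[!is.na(patch$values)]
  expect_true(all(vals == 3))
  expect_true(all(msk[!is.na(patch$values)]))  # patch within the mask
  # tiny mask -> radius error
  small <- make_ellipse_mask(10, 3, 0, shape = c(32L, 32L))
  geo_s <- list(mask = small, vein_point = c(15.5, 15.5), vein_dir = c(0, 1))
  expect_error(region_patch(param_map("u", matrix(1, 32, 32), small), geo_s),
               "radius")
})
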