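# Sampling supports on a leaf mask: the transect parallel to the main vein,
# the perpendicular transect at the widest point, and the largest inscribed
# near-circular region. Coordinates are 0-based (row, col) pixel centers.

#' Estimate the main-vein axis of a leaf mask
#'
#' The axis is the principal second-moment axis of the mask pixels through
#' the centroid, a surrogate for the anatomical main vein (strawberry
#' leaflets are elongated along it). The direction sign is normalized to a
#' positive first (row) component, or positive column component when the
#' row component is ~0. For nearly isotropic masks (principal axis ratio
#' < 1.05) the horizontal axis is returned with a warning.
#'
#' @param mask Logical matrix, >= 64 foreground pixels.
#' @return List with `vein_point` (centroid, 0-based c(row, col)),
#'   `vein_dir` (unit 2-vector), `axis_ratio`.
#' @export
estimate_vein_axis <- function(mask) {
  px <- which(mask, arr.ind = TRUE) - 1  # 0-based
  if (nrow(px) < 64) cp_stop("estimate_vein_axis(): degenerate mask (area %d < 64 px)", nrow(px))
  ctr <- colMeans(px)
  cc <- stats::cov(px)
  eg <- eigen(cc, symmetric = TRUE)
  ratio <- sqrt(eg$values[1] / max(eg$values[2], 1e-12))
  if (ratio < 1.05) {
    warning("estimate_vein_axis(): isotropic mask (axis ratio ",
            sprintf("%.3f", ratio), "), falling back to horizontal axis")
    dir <- c(0, 1)
  } else {
    dir <- eg$vectors[, 1]
  }
  # sign convention: positive first component (row), else positive column
  if (dir[1] < 0 || (abs(dir[1]) < 1e-12 && dir[2] < 0)) dir <- -dir
  list(vein_point = unname(ctr), vein_dir = unname(dir / sqrt(sum(dir^2))),
       axis_ratio = ratio)
}

# half-up rounding (round() ties-to-even collapses consecutive samples when
# coordinates fall on half-integers, e.g. lines through a raster centroid)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# Sample a map along the line through `point` with unit direction `dir`,
# unit-spaced with nearest-pixel lookup, and clip to the longest run of
# consecutive valid samples. Returns NULL if no sample is valid.
#' @noRd
line_profile <- function(map, point, dir, orientation) {
  vals <- map$values; msk <- map$mask
  nr <- nrow(vals); nc <- ncol(vals)
  t_max <- ceiling(sqrt(nr^2 + nc^2))
  tt <- seq(-t_max, t_max)
  rr <- round_half_up(point[1] + tt * dir[1])
  cc <- round_half_up(point[2] + tt * dir[2])
  # drop consecutive duplicate pixels (unit steps can round to the same px)
  keep <- c(TRUE, diff(rr) != 0 | diff(cc) != 0)
  rr <- rr[keep]; cc <- cc[keep]
  inside <- rr >= 0 & rr < nr & cc >= 0 & cc < nc
  ok <- inside
  ok[inside] <- msk[cbind(rr[inside] + 1, cc[inside] + 1)]
  run <- longest_run(ok)
  if (is.null(run) || run$len < 8)
    cp_stop("%s transect: longest valid run is %d px (< 8)",
            orientation, if (is.null(run)) 0L else run$len)
  sel <- run$start:(run$start + run$len - 1L)
  structure(list(
    values = vals[cbind(rr[sel] + 1, cc[sel] + 1)],
    pixel_coords = cbind(row = rr[sel], col = cc[sel]),
    orientation = orientation),
    class = "leaf_profile")
}

#' @noRd
longest_run <- function(ok) {
  r <- rle(ok)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  i <- which(r$values)[which.max(r$lengths[r$values])]
  list(start = ends[i] - r$lengths[i] + 1L, len = r$lengths[i])
}

#' @export
print.leaf_profile <- function(x, ...) {
  cat(sprintf("leaf_profile (%s): %d samples, range [%.4g, %.4g]\n",
              x$orientation, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Transect parallel to the main vein
#'
#' Samples the map along the line through the vein point in the vein
#' direction, unit-spaced with nearest-pixel lookup, clipped to the longest
#' run of consecutive valid pixels; both endpoints lie strictly inside the
#' valid mask.
#'
#' @param map A [param_map].
#' @param geometry A leaf geometry (from [make_leaf_geometry()] or any list
#'   with `vein_point` and `vein_dir`).
#' @return A `leaf_profile` (values, 0-based pixel coords, orientation).
#' @export
parallel_transect <- function(map, geometry) {
  stopifnot(inherits(map, "param_map"))
  line_profile(map, geometry$vein_point, geometry$vein_dir, "parallel")
}

#' Transect perpendicular to the main vein at the widest point
#'
#' The widest point is the position along the vein axis that maximizes the
#' length of the contiguous perpendicular chord through the geometry mask;
#' the profile is sampled along that chord (map validity applied as for
#' [parallel_transect()]).
#'
#' @inheritParams parallel_transect
#' @return A `leaf_profile` with orientation "perpendicular".
#' @export
perpendicular_transect <- function(map, geometry) {
  stopifnot(inherits(map, "param_map"))
  dir <- geometry$vein_dir
  pdir <- c(-dir[2], dir[1])
  if (!is.null(geometry$widest_point))  # precomputed by make_leaf_geometry()
    return(line_profile(map, geometry$widest_point, pdir, "perpendicular"))
  best <- widest_chord_point(geometry)
  line_profile(map, best, pdir, "perpendicular")
}

# Axis position (0-based point) maximizing the contiguous perpendicular
# chord length through the mask.
#' @noRd
widest_chord_point <- function(geometry) {
  msk <- geometry$mask
  nr <- nrow(msk); nc <- ncol(msk)
  dir <- geometry$vein_dir
  pdir <- c(-dir[2], dir[1])
  t_max <- ceiling(sqrt(nr^2 + nc^2))
  # scan axis positions for the longest contiguous perpendicular mask chord;
  # positions are visited from the centroid outwards so that among tied
  # chord lengths the one nearest the centroid wins
  best <- NULL; best_len <- -1L
  for (t in order(abs(seq(-t_max, t_max))) - t_max - 1L) {
    p <- geometry$vein_point + t * dir
    r0 <- round_half_up(p[1]); c0 <- round_half_up(p[2])
    if (r0 < 0 || r0 >= nr || c0 < 0 || c0 >= nc || !msk[r0 + 1, c0 + 1]) next
    ss <- seq(-t_max, t_max)
    rr <- round_half_up(p[1] + ss * pdir[1])
    cc <- round_half_up(p[2] + ss * pdir[2])
    inside <- rr >= 0 & rr < nr & cc >= 0 & cc < nc
    ok <- inside
    ok[inside] <- msk[cbind(rr[inside] + 1, cc[inside] + 1)]
    # contiguous run through the axis point (ss == 0 at index t_max + 1)
    run <- run_through(ok, t_max + 1L)
    if (!is.null(run) && run$len > best_len) {
      best_len <- run$len
      best <- p
    }
  }
  if (is.null(best)) cp_stop("perpendicular transect: no valid axis position")
  best
}

# longest TRUE run containing index `at` (or NULL)
#' @noRd
run_through <- function(ok, at) {
  if (!ok[at]) return(NULL)
  s <- at; while (s > 1L && ok[s - 1L]) s <- s - 1L
  e <- at; while (e < length(ok) && ok[e + 1L]) e <- e + 1L
  list(start = s, len = e - s + 1L)
}

#' Largest inscribed near-circular region of the leaf
#'
#' Finds the maximum of the Euclidean distance transform of the geometry
#' mask (the incircle), and returns the map values on the inscribed disk
#' intersected with the map's validity mask.
#'
#' @inheritParams parallel_transect
#' @return An object of class `region_patch`: `values` (full-size matrix,
#'   NA outside the disk/mask), `center` (0-based c(row, col)), `radius`
#'   (pixels), `n_valid`.
#' @export
region_patch <- function(map, geometry) {
  stopifnot(inherits(map, "param_map"))
  msk <- geometry$mask
  if (!is.null(geometry$region_center)) {  # precomputed by make_leaf_geometry()
    ctr <- geometry$region_center
    radius <- geometry$region_radius
  } else {
    dt <- mask_distance_transform(msk)
    i <- which.max(dt)
    radius <- dt[i]
    ctr <- c((i - 1) %% nrow(msk), (i - 1) %/% nrow(msk))  # 0-based (row, col)
  }
  if (radius < 4) cp_stop("region_patch(): inscribed radius %.2f px < 4", radius)
  rows <- matrix(0:(nrow(msk) - 1), nrow(msk), ncol(msk))
  cols <- matrix(0:(ncol(msk) - 1), nrow(msk), ncol(msk), byrow = TRUE)
  disk <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= radius^2
  valid <- disk & map$mask
  v <- map$values
  v[!valid] <- NA_real_
  if (sum(valid) < 0.4 * sum(msk))
    cp_log("region_patch: disk covers %.0f%% of the mask (< 40%%)",
           100 * sum(valid) / sum(msk))
  structure(list(values = v, center = ctr, radius = radius,
                 n_valid = sum(valid)),
            class = "region_patch")
}

# Exact Euclidean distance from each mask pixel to the nearest non-mask
# pixel (image border counts as background just outside the frame).
#' @noRd
mask_distance_transform <- function(msk) {
  nr <- nrow(msk); nc <- ncol(msk)
  fg <- which(msk, arr.ind = TRUE)
  if (nrow(fg) == 0) cp_stop("mask_distance_transform(): empty mask")
  # background limited to non-mask pixels 4-adjacent to the mask: the
  # nearest background pixel to any foreground pixel is on that boundary
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  near_fg <- shift(msk, 1, 0) | shift(msk, -1, 0) | shift(msk, 0, 1) | shift(msk, 0, -1)
  bg <- which(!msk & near_fg, arr.ind = TRUE)
  dt <- matrix(0, nr, nc)
  if (nrow(bg) > 0) {
    d2 <- outer(fg[, 1], bg[, 1], `-`)^2 + outer(fg[, 2], bg[, 2], `-`)^2
    dmin <- sqrt(apply(d2, 1, min))
  } else {
    dmin <- rep(Inf, nrow(fg))
  }
  # cap by distance to the image border (background outside the frame)
  border <- pmin(fg[, 1] - 1 + 1, nr - fg[, 1] + 1, fg[, 2] - 1 + 1, nc - fg[, 2] + 1)
  dt[fg] <- pmin(dmin, border)
  dt
}
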