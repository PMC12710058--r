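# Synthetic leaf geometry: a noisy-ellipse mask with precomputed sampling
# supports (vein axis, widest perpendicular chord, inscribed disk).

#' Generate a synthetic leaf mask and its sampling geometry
#'
#' The leaf outline is an ellipse with semi-axes `a >= b`, rotated by
#' `rotation_deg`, with a smooth periodic perturbation of the boundary
#' radius (relative amplitude `boundary_noise`) to mimic lobed leaf
#' margins. The vein axis, the widest perpendicular chord and the largest
#' inscribed disk are computed once and stored, so that all parameter maps
#' of one plant share identical sampling supports.
#'
#' @param a,b Ellipse semi-axes in pixels (>= 8).
#' @param rotation_deg Rotation of the major axis, degrees counterclockwise
#'   from the column (horizontal) direction.
#' @param boundary_noise Relative amplitude of the boundary perturbation
#'   (0 = exact ellipse; default 0.05).
#' @param shape Raster size `c(rows, cols)` (default 64 x 64).
#' @param seed Integer seed for the boundary perturbation.
#' @return A `leaf_geometry` list: `mask`, `vein_point`, `vein_dir`,
#'   `widest_point`, `widest_chord`, `region_center`, `region_radius`.
#' @export
make_leaf_geometry <- function(a = 26, b = 16, rotation_deg = 0,
                               boundary_noise = 0.05, shape = c(64L, 64L),
                               seed = 1L) {
  if (a < 8 || b < 8) cp_stop("make_leaf_geometry(): semi-axes must be >= 8 px")
  set.seed(as.integer(seed))
  nr <- shape[1]; nc <- shape[2]
  ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  th <- rotation_deg * pi / 180
  rows <- matrix(0:(nr - 1), nr, nc) - ctr[1]
  cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE) - ctr[2]
  # coordinates in the ellipse frame: u along the major axis (columns at 0 deg)
  u <- cols * cos(th) + rows * sin(th)
  v <- -cols * sin(th) + rows * cos(th)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  if (boundary_noise > 0) {
    # low-order harmonic perturbation of the boundary radius
    ang <- atan2(v / b, u / a)
    k <- 2:5
    amp <- stats::rnorm(length(k), 0, boundary_noise / sqrt(length(k)))
    phs <- stats::runif(length(k), 0, 2 * pi)
    pert <- Reduce(`+`, Map(function(kk, aa, pp) aa * cos(kk * ang + pp),
                            k, amp, phs))
    rho <- rho * (1 + pert)
  }
  mask <- rho <= 1
  if (sum(mask) < 64)
    cp_stop("make_leaf_geometry(): degenerate mask (area %d < 64 px)", sum(mask))

  axis <- estimate_vein_axis(mask)
  geo <- list(mask = mask, vein_point = axis$vein_point,
              vein_dir = axis$vein_dir, axis_ratio = axis$axis_ratio)
  # widest perpendicular chord (precomputed, shared by all maps)
  geo$widest_point <- widest_chord_point(geo)
  unit_map <- param_map("unit", matrix(1, nr, nc), mask)
  prof <- line_profile(unit_map, geo$widest_point,
                       c(-geo$vein_dir[2], geo$vein_dir[1]), "perpendicular")
  geo$widest_chord <- prof$pixel_coords[c(1, nrow(prof$pixel_coords)), ]
  # largest inscribed disk
  dt <- mask_distance_transform(mask)
  i <- which.max(dt)
  geo$region_radius <- dt[i]
  geo$region_center <- c((i - 1) %% nr, (i - 1) %/% nr)
  class(geo) <- "leaf_geometry"
  geo
}

#' @export
print.leaf_geometry <- function(x, ...) {
  cat(sprintf(
    "leaf_geometry: %dx%d, area %d px, vein dir (%.3f, %.3f), incircle r = %.1f px\n",
    nrow(x$mask), ncol(x$mask), sum(x$mask), x$vein_dir[1], x$vein_dir[2],
    x$region_radius))
  invisible(x)
}

#' Vein-axis length of a geometry (longest run along the vein)
#' @noRd
vein_axis_length <- function(geometry) {
  unit_map <- param_map("unit",
                        matrix(1, nrow(geometry$mask), ncol(geometry$mask)),
                        geometry$mask)
  length(parallel_transect(unit_map, geometry)$values)
}
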