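# Inverse simulators: from target parameter fields to raw fluorescence
# frames / band reflectances, exact at zero noise so that the map module
# round-trips the targets.

#' Fluorescence frame-set container
#'
#' @param fo,fm,fo_p,fm_p,fs Rasters (matrices) in arbitrary fluorescence
#'   units, identical shape.
#' @param geometry A `leaf_geometry`.
#' @return An object of class `fluor_frame_set`.
#' @export
fluor_frame_set <- function(fo, fm, fo_p, fm_p, fs, geometry) {
  dims <- dim(fo)
  for (f in list(fm, fo_p, fm_p, fs))
    if (!all(dim(f) == dims)) cp_stop("fluor_frame_set(): frame shape mismatch")
  structure(list(fo = fo, fm = fm, fo_p = fo_p, fm_p = fm_p, fs = fs,
                 geometry = geometry),
            class = "fluor_frame_set")
}

#' Band-image container
#'
#' @param blue,green,red,nir Reflectance rasters in `[0, 1]`, identical shape.
#' @param geometry A `leaf_geometry`.
#' @return An object of class `band_set` carrying the four fixed nm windows
#'   (475-485, 545-555, 645-655, 780-790).
#' @export
band_set <- function(blue, green, red, nir, geometry) {
  dims <- dim(blue)
  for (f in list(green, red, nir))
    if (!all(dim(f) == dims)) cp_stop("band_set(): band shape mismatch")
  structure(list(blue = blue, green = green, red = red, nir = nir,
                 geometry = geometry,
                 window_nm = list(blue = c(475, 485), green = c(545, 555),
                                  red = c(645, 655), nir = c(780, 790))),
            class = "band_set")
}

#' Simulate PAM fluorescence frames from target quenching-parameter fields
#'
#' Inverts the parameter definitions: given pointwise targets for the
#' quantum-yield partition (Y(II), Y(NPQ), Y(NO), summing to 1), the
#' photochemical quenching coefficient qP and the dark-adapted maximum
#' yield Fv/Fm, the five frames are reconstructed (with `Fm = fm_scale`):
#' `Fm' = Fm * Y(NO) / (1 - Y(II))`, `Fs = Fm' (1 - Y(II))`,
#' `Fo' = Fm' (1 - Y(II)/qP)`, `Fo = Fm (1 - Fv/Fm)`. At `noise_sd = 0`
#' recomputing the parameter maps from the frames reproduces the targets to
#' machine precision. Multiplicative log-normal pixel noise (`noise_sd` as a
#' fraction) and a fraction of corrupted pixels (zeros / saturation)
#' exercise the cleaning stage.
#'
#' @param geometry A `leaf_geometry`.
#' @param target_maps List of full-size matrices `yii`, `ynpq`, `yno`,
#'   `qp`, and optionally `fvfm` (default 0.8). Must satisfy pointwise
#'   `yii + ynpq + yno = 1` (tolerance 1e-6), all in `[0, 1]`, and
#'   `qp > yii` inside the mask.
#' @param noise_sd Fractional pixel noise (default 0).
#' @param abnormal_frac Fraction of mask pixels corrupted (default 0).
#' @param fm_scale Fm level in instrument units (default 1000).
#' @param seed Integer seed.
#' @return A [fluor_frame_set()].
#' @export
simulate_fluorescence <- function(geometry, target_maps, noise_sd = 0,
                                  abnormal_frac = 0, fm_scale = 1000,
                                  seed = 1L) {
  m <- geometry$mask
  yii <- target_maps$yii; ynpq <- target_maps$ynpq; yno <- target_maps$yno
  qp <- target_maps$qp
  fvfm <- target_maps$fvfm %||% (m * 0 + 0.8)
  s <- yii[m] + ynpq[m] + yno[m]
  if (any(abs(s - 1) > 1e-6))
    cp_stop("simulate_fluorescence(): Y(II)+Y(NPQ)+Y(NO) != 1 (max dev %.2g)",
            max(abs(s - 1)))
  if (any(yii[m] < 0) || any(ynpq[m] < 0) || any(yno[m] <= 0))
    cp_stop("simulate_fluorescence(): yields must be >= 0 (Y(NO) > 0)")
  if (any(qp[m] <= yii[m]))
    cp_stop("simulate_fluorescence(): need qP > Y(II) pointwise for Fo' > 0")
  if (any(fvfm[m] <= 0 | fvfm[m] >= 1))
    cp_stop("simulate_fluorescence(): Fv/Fm targets must lie in (0, 1)")

  fm   <- matrix(fm_scale, nrow(m), ncol(m))
  fm_p <- fm * yno / (1 - yii)
  fs   <- fm_p * (1 - yii)
  fo_p <- fm_p * (1 - yii / qp)
  fo   <- fm * (1 - fvfm)

  set.seed(as.integer(seed))
  frames <- list(fo = fo, fm = fm, fo_p = fo_p, fm_p = fm_p, fs = fs)
  if (noise_sd > 0) {
    frames <- lapply(frames, function(f) {
      f * exp(matrix(stats::rnorm(length(f), 0, noise_sd), nrow(f)))
    })
  }
  if (abnormal_frac > 0) {
    idx <- which(m)
    n_bad <- round(abnormal_frac * length(idx))
    if (n_bad > 0) {
      bad <- sample(idx, n_bad)
      half <- seq_len(ceiling(n_bad / 2))
      for (nm in names(frames)) {
        f <- frames[[nm]]
        f[bad[half]] <- 0                      # dead pixels
        f[bad[-half]] <- fm_scale * 10         # saturated pixels
        frames[[nm]] <- f
      }
    }
  }
  outside <- !m
  frames <- lapply(frames, function(f) { f[outside] <- 0; f })
  fluor_frame_set(frames$fo, frames$fm, frames$fo_p, frames$fm_p, frames$fs,
                  geometry)
}

#' Simulate band reflectance images from target index fields
#'
#' Inverts the normalized-difference definitions: given target fields for
#' the three NIR-based indices (`ndvi`, `ndving`, `ndvinb`, all in (-1, 1))
#' and an NIR reflectance field, each visible band is
#' `x = NIR (1 - I) / (1 + I)`. The two green-based indices follow
#' deterministically. At zero noise the recomputed target indices match to
#' machine precision.
#'
#' @param geometry A `leaf_geometry`.
#' @param target_indices List of full-size matrices `ndvi`, `ndving`,
#'   `ndvinb` in (-1, 1), and optionally `nir` in (0, 1] (default 0.55).
#' @param noise_sd Additive Gaussian reflectance noise sd (default 0).
#' @param seed Integer seed.
#' @return A [band_set()].
#' @export
simulate_bands <- function(geometry, target_indices, noise_sd = 0, seed = 1L) {
  m <- geometry$mask
  nir <- target_indices$nir %||% (m * 0 + 0.55)
  for (nm in c("ndvi", "ndving", "ndvinb")) {
    ti <- target_indices[[nm]]
    if (is.null(ti)) cp_stop("simulate_bands(): missing target '%s'", nm)
    if (any(abs(ti[m]) >= 1))
      cp_stop("simulate_bands(): target '%s' outside (-1, 1)", nm)
  }
  inv <- function(I) nir * (1 - I) / (1 + I)
  red   <- inv(target_indices$ndvi)
  green <- inv(target_indices$ndving)
  blue  <- inv(target_indices$ndvinb)
  bands <- list(blue = blue, green = green, red = red, nir = nir)
  if (any(vapply(bands, function(b) any(b[m] < 0 | b[m] > 1), logical(1))))
    cp_stop("simulate_bands(): implied reflectance outside [0, 1]; lower nir or soften indices")
  set.seed(as.integer(seed))
  if (noise_sd > 0) {
    bands <- lapply(bands, function(b) {
      clamp(b + matrix(stats::rnorm(length(b), 0, noise_sd), nrow(b)), 0, 1)
    })
  }
  outside <- !m
  bands <- lapply(bands, function(b) { b[outside] <- 0; b })
  band_set(bands$blue, bands$green, bands$red, bands$nir, geometry)
}
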