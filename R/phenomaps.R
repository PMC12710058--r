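# Phenotypic parameter maps: 8 chlorophyll-fluorescence quenching parameters
# from the five PAM frames, and 5 normalized-difference spectral indices from
# the four band-mean reflectance images.

#' Construct a named phenotypic parameter map
#'
#' @param name One of the 13 canonical parameter names (see `ALL_PARAMS`).
#' @param values Numeric raster (matrix).
#' @param mask Logical matrix of valid pixels, same shape.
#' @return An object of class `param_map`.
#' @export
param_map <- function(name, values, mask) {
  stopifnot(is.matrix(values), is.logical(mask), all(dim(values) == dim(mask)))
  structure(list(name = name, values = values, mask = mask), class = "param_map")
}

#' @export
print.param_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("param_map '%s': %dx%d raster, %d valid px, range [%.4g, %.4g]\n",
              x$name, nrow(x$values), ncol(x$values), sum(x$mask),
              min(v), max(v)))
  invisible(x)
}

#' Remove abnormal pixels from a fluorescence frame set
#'
#' A pixel is kept only if all five frames are finite and satisfy the
#' physical ordering of PAM fluorescence: `Fm >= Fo > 0`, `Fm' >= Fo' > 0`,
#' `Fm >= Fm'`, `Fm' >= Fs`. Pixels failing any check are dropped from the
#' validity mask. If fewer than 50 % of the leaf-mask pixels survive, an
#' error names the most frequently violated invariant.
#'
#' @param frames A [fluor_frame_set()].
#' @return The frame set with its geometry mask replaced by the cleaned
#'   validity mask, and an attribute `n_removed`.
#' @export
clean_frames <- function(frames) {
  stopifnot(inherits(frames, "fluor_frame_set"))
  m <- frames$geometry$mask
  checks <- list(
    "non-finite frame value" = Reduce(`&`, lapply(
      frames[c("fo", "fm", "fo_p", "fm_p", "fs")], function(f) is.finite(f))),
    "Fo <= 0"   = frames$fo > 0,
    "Fo' <= 0"  = frames$fo_p > 0,
    "Fm < Fo"   = frames$fm >= frames$fo,
    "Fm' < Fo'" = frames$fm_p >= frames$fo_p,
    "Fm < Fm'"  = frames$fm >= frames$fm_p,
    "Fm' < Fs"  = frames$fm_p >= frames$fs)
  ok <- Reduce(`&`, checks)
  ok[is.na(ok)] <- FALSE
  valid <- m & ok
  n_leaf <- sum(m)
  if (sum(valid) < 0.5 * n_leaf) {
    viol <- vapply(checks, function(ch) sum(m & !(ch %in% TRUE)), numeric(1))
    cp_stop("clean_frames(): only %d/%d leaf pixels survive cleaning (worst invariant: %s)",
            sum(valid), n_leaf, names(which.max(viol)))
  }
  out <- frames
  out$geometry$mask <- valid
  attr(out, "n_removed") <- n_leaf - sum(valid)
  out
}

#' Compute the eight chlorophyll-fluorescence parameter maps
#'
#' Pointwise over the cleaned validity mask (lake-model forms):
#' `Fv/Fm = (Fm-Fo)/Fm`, `Y(II) = (Fm'-Fs)/Fm'`, `NPQ = Fm/Fm' - 1`,
#' `qP = (Fm'-Fs)/(Fm'-Fo')`, `qL = qP * Fo'/Fs`, `Y(NO) = Fs/Fm`,
#' `Y(NPQ) = Fs/Fm' - Fs/Fm`, and `qN = (Fm-Fm')/(Fm-Fo)` (or the
#' alternative `1 - (Fm'-Fo')/(Fm-Fo)` via `qn_form`). These forms satisfy
#' the energy-partition identity `Y(II)+Y(NPQ)+Y(NO) = 1` algebraically.
#' Pixels with a zero denominator are dropped from the map masks and logged.
#'
#' @param frames A cleaned [fluor_frame_set()] (see [clean_frames()]).
#' @param qn_form `"fm"` (default) for `(Fm-Fm')/(Fm-Fo)`, `"fo"` for
#'   `1-(Fm'-Fo')/(Fm-Fo)`.
#' @return Named list of 8 [param_map] objects.
#' @export
fluorescence_maps <- function(frames, qn_form = c("fm", "fo")) {
  qn_form <- match.arg(qn_form)
  stopifnot(inherits(frames, "fluor_frame_set"))
  m <- frames$geometry$mask
  fo <- frames$fo; fm <- frames$fm; fo_p <- frames$fo_p
  fm_p <- frames$fm_p; fs <- frames$fs

  denom_ok <- fm > 0 & fm_p > 0 & (fm_p - fo_p) > 0 & fs > 0 & (fm - fo) > 0
  valid <- m & denom_ok
  n_drop <- sum(m) - sum(valid)
  if (n_drop > 0)
    cp_log("fluorescence_maps: dropped %d pixel(s) with zero denominators", n_drop)

  qp <- (fm_p - fs) / (fm_p - fo_p)
  maps <- list(
    "Fv/Fm"  = (fm - fo) / fm,
    "NPQ"    = fm / fm_p - 1,
    "qP"     = qp,
    "qL"     = qp * fo_p / fs,
    "qN"     = if (qn_form == "fm") (fm - fm_p) / (fm - fo)
               else 1 - (fm_p - fo_p) / (fm - fo),
    "Y(II)"  = (fm_p - fs) / fm_p,
    "Y(NPQ)" = fs / fm_p - fs / fm,
    "Y(NO)"  = fs / fm)
  lapply(names(maps), function(nm) {
    v <- maps[[nm]]
    v[!valid] <- NA_real_
    param_map(nm, v, valid)
  }) |> stats::setNames(names(maps))
}

#' Band-mean reflectance image from a reflectance cube
#'
#' Unweighted mean over all native cube bands whose center wavelength lies
#' in the closed window.
#'
#' @param cube 3D array (rows x cols x bands) with the band-center
#'   wavelengths (nm, strictly increasing) in `dimnames` or supplied via
#'   `wavelengths_nm`.
#' @param window_nm Length-2 numeric interval in nm, e.g. `c(780, 790)`.
#' @param wavelengths_nm Optional numeric vector of band centers.
#' @return Numeric matrix (mean reflectance raster); attribute `n_bands`
#'   gives the number of averaged bands.
#' @export
band_mean <- function(cube, window_nm, wavelengths_nm = NULL) {
  stopifnot(length(dim(cube)) == 3, length(window_nm) == 2)
  wl <- wavelengths_nm %||% as.numeric(dimnames(cube)[[3]])
  if (is.null(wl) || any(is.na(wl)) || length(wl) != dim(cube)[3])
    cp_stop("band_mean(): band-center wavelengths missing or malformed")
  if (any(diff(wl) <= 0))
    cp_stop("band_mean(): wavelength axis must be strictly increasing")
  sel <- which(wl >= window_nm[1] & wl <= window_nm[2])
  if (length(sel) == 0)
    cp_stop("band_mean(): no band centers inside [%g, %g] nm",
            window_nm[1], window_nm[2])
  out <- apply(cube[, , sel, drop = FALSE], c(1, 2), mean)
  attr(out, "n_bands") <- length(sel)
  out
}

#' Normalized-difference index map
#'
#' `(a - b) / (a + b)` pointwise; pixels with `a + b = 0` are dropped from
#' the mask.
#'
#' @param a,b Reflectance rasters of identical shape.
#' @param mask Logical validity mask (default: all pixels).
#' @param name Parameter name for the resulting map (default "ND").
#' @return A [param_map] with values in `[-1, 1]`.
#' @export
nd_index <- function(a, b, mask = NULL, name = "ND") {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
    cp_stop("nd_index(): rasters must be matrices of identical shape")
  mask <- mask %||% matrix(TRUE, nrow(a), ncol(a))
  s <- a + b
  valid <- mask & is.finite(s) & s != 0
  v <- (a - b) / s
  v[!valid] <- NA_real_
  param_map(name, v, valid)
}

#' The five normalized-difference spectral index maps
#'
#' NDVI = (NIR-R)/(NIR+R), NDVInb = (NIR-B)/(NIR+B), NDVIng = (NIR-G)/(NIR+G),
#' NDVIgb = (G-B)/(G+B), NDVIgr = (G-R)/(G+R).
#'
#' @param bands A [band_set()].
#' @return Named list of 5 [param_map] objects.
#' @export
spectral_index_maps <- function(bands) {
  stopifnot(inherits(bands, "band_set"))
  m <- bands$geometry$mask
  list(
    "NDVI"   = nd_index(bands$nir,   bands$red,   m, "NDVI"),
    "NDVInb" = nd_index(bands$nir,   bands$blue,  m, "NDVInb"),
    "NDVIng" = nd_index(bands$nir,   bands$green, m, "NDVIng"),
    "NDVIgb" = nd_index(bands$green, bands$blue,  m, "NDVIgb"),
    "NDVIgr" = nd_index(bands$green, bands$red,   m, "NDVIgr"))
}

#' All 13 parameter maps of one synthetic sample
#'
#' Cleans the fluorescence frames, computes the 8 fluorescence maps and the
#' 5 spectral index maps.
#'
#' @param smp One sample of a `cold_dataset`.
#' @return Named list of 13 [param_map] objects in canonical order.
#' @export
sample_param_maps <- function(smp) {
  cleaned <- clean_frames(smp$frames)
  c(fluorescence_maps(cleaned), spectral_index_maps(smp$bands))
}
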