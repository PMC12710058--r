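# Full synthetic experiments: the treatment factorial with ground-truth
# physiology, raw physiological measurements that the physio module inverts
# exactly, and leaf rasters whose spatial heterogeneity responds to stress.

# ---------------------------------------------------------------------------
# Treatment-level physiological means.
#
# REC and Chl_a+b cell means follow the published trends (REC rises with
# dose and plateaus under the two coldest gradients; Chl declines under
# mild gradients and shows the transient T4D1/T4D2 increase); P_max is then
# solved per cell from the published PPPI group mean, so the synthetic
# world reproduces the printed PPPI table in expectation. The control cell
# uses the physiology reconstructed from the printed percentage relations.
#' @noRd
treatment_means <- function() {
  ck <- reconstruct_control()
  recs <- list(CK = rep(ck["rec"], 3),
               T1 = c(0.250, 0.300, 0.320),
               T2 = c(0.315, 0.330, 0.350),
               T3 = c(0.324, 0.352, 0.352),
               T4 = c(0.333, 0.384, 0.384))
  chls <- list(CK = rep(ck["chl"], 3),
               T1 = c(2.850, 2.800, 2.750),
               T2 = c(2.750, 2.550, 2.329),
               T3 = c(2.700, 2.500, 2.329),
               T4 = c(3.260, 3.025, 2.163))
  ref <- reference_physiology()
  # PPPI is affine in (P_max, REC, Chl): PPPI = cP*P + cR*R + cC*C - 5
  cf <- drop(PPPI_WEIGHTS %*% t(PPPI_LOADINGS))
  rows <- list()
  for (tn in c("CK", "T1", "T2", "T3", "T4")) {
    for (d in 1:3) {
      lab <- if (tn == "CK") sprintf("CKD%d", d) else sprintf("%sD%d", tn, d)
      rec_m <- recs[[tn]][d]; chl_m <- chls[[tn]][d]
      if (tn == "CK") {
        pmax_m <- unname(ck["p_max"])
      } else {
        target <- ref$pppi_mean[sprintf("%sD%d", tn, d)]
        pmax_m <- unname((target - PPPI_INTERCEPT -
                            cf["REC"] * rec_m - cf["Chl_a+b"] * chl_m) / cf["P_max"])
      }
      rows[[lab]] <- data.frame(cell = lab, temp = tn, duration_index = d,
                                p_max = pmax_m, rec = unname(rec_m),
                                chl = unname(chl_m))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Smooth correlated noise field, standardized to unit sd.
#' @noRd
smooth_noise_field <- function(nr, nc, corr_len = 3) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- stats::dnorm(seq(-3, 3, length.out = 2 * corr_len + 1))
  k <- k / sum(k)
  pad_filter <- function(m) {
    # separable smoothing with edge replication
    sm <- apply(m, 2, function(col) stats::filter(col, k, sides = 2))
    sm <- t(apply(t(sm), 2, function(row) stats::filter(row, k, sides = 2)))
    sm[is.na(sm)] <- 0
    sm
  }
  z <- pad_filter(z)
  z / max(stats::sd(z), 1e-12)
}

# structure-preserving clamp (pmin/pmax with a leading scalar drop dim)
#' @noRd
clamp <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# Per-sample target parameter fields. The leaf carries a fixed base-to-tip
# gradient along the vein; stress raises the amplitude of the spatially
# correlated heterogeneity relative to that gradient, which is what the
# min-max-quantized texture features respond to.
#' @noRd
make_target_fields <- function(geometry, sev) {
  m <- geometry$mask
  nr <- nrow(m); nc <- ncol(m)
  rows <- matrix(0:(nr - 1), nr, nc); cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  dirv <- geometry$vein_dir
  u <- (rows - geometry$vein_point[1]) * dirv[1] +
       (cols - geometry$vein_point[2]) * dirv[2]
  u <- u / max(abs(u[m]))          # [-1, 1] along the vein
  ug <- (u + 1) / 2                # 0 at base, 1 at tip

  rough <- function(s) 0.015 + 0.10 * clamp(s, 0, 1)
  z <- function() smooth_noise_field(nr, nc)

  yii   <- clamp(0.55 - 0.28 * sev["pmax"] - 0.06 * ug + rough(sev["pmax"]) * z(),
                 0.05, 0.78)
  qfrac <- clamp(0.60 - 0.25 * sev["chl"] - 0.08 * ug + rough(sev["chl"]) * z(),
                 0.08, 0.95)
  rr    <- clamp(0.40 + 0.25 * sev["rec"] + 0.05 * ug + rough(sev["rec"]) * z(),
                 0.12, 0.90)
  fvfm  <- clamp(0.82 - 0.08 * sev["chl"] - 0.02 * ug + 0.010 * z(),
                 0.55, 0.92)
  ndvi   <- clamp(0.75 - 0.25 * sev["dose"] - 0.05 * ug +
                    (0.010 + 0.08 * sev["dose"]) * z(), 0.10, 0.92)
  ndving <- clamp(0.55 - 0.20 * sev["dose"] - 0.04 * ug +
                    (0.010 + 0.08 * sev["dose"]) * z(), 0.10, 0.90)
  ndvinb <- clamp(0.65 - 0.20 * sev["dose"] - 0.04 * ug +
                    (0.010 + 0.08 * sev["dose"]) * z(), 0.10, 0.90)

  list(fluor = list(yii = yii,
                    ynpq = (1 - yii) * (1 - rr),
                    yno = (1 - yii) * rr,
                    qp = yii + (1 - yii) * qfrac,
                    fvfm = fvfm),
       spectral = list(ndvi = ndvi, ndving = ndving, ndvinb = ndvinb,
                       nir = matrix(0.50, nr, nc)))
}

# Raw physiology implied by true (p_max, rec, chl): the physio module must
# recover the truth exactly at zero noise. Fixed bench constants: C2 = 200
# uS/cm, V = 25 mL, D = 1, m = 0.2 g, A665/A649 = 1.2, and a light-response
# curve from the modified rectangular hyperbola with beta = 3e-4,
# gamma = 1.5e-3, Rd = 0.8 (alpha solved from the target P_max).
#' @noRd
make_raw_physio <- function(p_max, rec_v, chl_v, noise_scale = 0) {
  C2 <- 200
  A_ratio <- 1.2
  # chlorophyll(A649, A665): c_a+c_b = 6.63*A665 + 18.08*A649; content = sum/8
  A649 <- 8 * chl_v / (6.63 * A_ratio + 18.08)
  A665 <- A_ratio * A649
  beta <- 3e-4; gamma <- 1.5e-3; Rd <- 0.8
  i_opt <- (sqrt((beta + gamma) / beta) - 1) / gamma
  k <- (1 - beta * i_opt) / (1 + gamma * i_opt) * i_opt
  alpha <- (p_max + Rd) / k
  I <- c(1600, 1400, 1200, 1000, 800, 600, 400, 200, 100, 50, 20, 0)
  Pn <- alpha * (1 - beta * I) / (1 + gamma * I) * I - Rd
  if (noise_scale > 0) Pn <- Pn + stats::rnorm(length(I), 0, 0.10 * noise_scale)
  list(C1 = rec_v * C2, C2 = C2, A649 = A649, A665 = A665,
       V_mL = 25, D = 1, m_g = 0.2, light_I = I, light_Pn = Pn)
}

#' Build a complete synthetic cold-stress experiment
#'
#' One sample per (treatment x duration x replicate), including the control
#' at each duration. Per sample: a leaf geometry, five fluorescence frames,
#' four band reflectance images, the hourly temperature profile of its
#' treatment, raw physiological measurements, and the ground truth
#' (P_max, REC, Chl_a+b, PPPI, RNAT, CDRI, risk level, latent severities).
#'
#' Treatment-cell means follow the published factorial (see
#' [reference_physiology()]); replicate scatter, pixel noise and corrupted
#' pixels scale with `noise_scale` (0 = exact means, noise-free rasters).
#'
#' @param designs List of [treatment_design()]s (default the full factorial).
#' @param replicates Replicates per cell (>= 1).
#' @param seed Integer master seed.
#' @param noise_scale Global noise multiplier (default 1; 0 = deterministic
#'   means and noise-free rasters).
#' @param shape Raster size (default 64 x 64).
#' @param abnormal_frac Fraction of corrupted mask pixels (default 0.01,
#'   scaled by `noise_scale`).
#' @param rasters If `FALSE`, skip leaf geometry and raster synthesis and
#'   generate only physiology/ground truth (for cheap large-replicate
#'   statistical checks).
#' @return A `cold_dataset`: list with `samples` (list), `ground_truth`
#'   (data.frame), `profiles` (temperature profiles per design label),
#'   `config`.
#' @export
build_dataset <- function(designs = factorial_designs(), replicates = 3L,
                          seed = 1L, noise_scale = 1, shape = c(64L, 64L),
                          abnormal_frac = 0.01, rasters = TRUE) {
  if (replicates < 1) cp_stop("build_dataset(): replicates must be >= 1")
  means <- treatment_means()
  ck <- reconstruct_control()
  profiles <- lapply(designs, make_temperature_profile)
  # control profile per duration (for RNAT)
  durations <- vapply(designs, `[[`, integer(1), "duration_days")
  ck_profiles <- lapply(unique(durations), function(d)
    make_temperature_profile(treatment_design(25, 15, d, sprintf("CK_%dd", d),
                                              TRUE)))
  names(ck_profiles) <- as.character(unique(durations))

  samples <- list()
  gt <- list()
  idx <- 0L
  for (di in seq_along(designs)) {
    des <- designs[[di]]
    lab <- des$label
    cell <- means[means$cell == lab, ]
    if (nrow(cell) != 1) {
      # non-factorial custom design: interpolate means from the dose
      cp_stop("build_dataset(): no treatment means defined for design '%s'", lab)
    }
    rnat_true <- rnat(ck_profiles[[as.character(des$duration_days)]],
                      profiles[[di]])
    for (rep_i in seq_len(replicates)) {
      idx <- idx + 1L
      sseed <- child_seed(seed, idx)
      set.seed(sseed)
      p_max_t <- cell$p_max + stats::rnorm(1, 0, 0.45 * noise_scale)
      rec_t   <- cell$rec  + stats::rnorm(1, 0, 0.012 * noise_scale)
      chl_t   <- cell$chl  + stats::rnorm(1, 0, 0.090 * noise_scale)
      p_max_t <- clamp(p_max_t, 0.5, 25)
      rec_t   <- clamp(rec_t, 0.02, 0.98)
      chl_t   <- clamp(chl_t, 0.30, 4.5)

      sev <- c(pmax = clamp((ck["p_max"] - p_max_t) / (ck["p_max"] - 8.0), 0, 1),
               rec  = clamp((rec_t - ck["rec"]) / (0.40 - ck["rec"]), 0, 1),
               chl  = clamp((3.30 - chl_t) / (3.30 - 2.00), 0, 1),
               dose = clamp(rnat_true / 3240, 0, 1))
      names(sev) <- c("pmax", "rec", "chl", "dose")

      if (rasters) {
        geo <- make_leaf_geometry(
          a = 26 + stats::runif(1, -2, 2), b = 16 + stats::runif(1, -1.5, 1.5),
          rotation_deg = stats::runif(1, 0, 180), boundary_noise = 0.04,
          shape = shape, seed = child_seed(sseed, 1))
        set.seed(child_seed(sseed, 2))
        fields <- make_target_fields(geo, sev)
        frames <- simulate_fluorescence(
          geo, fields$fluor, noise_sd = 0.01 * noise_scale,
          abnormal_frac = abnormal_frac * noise_scale,
          seed = child_seed(sseed, 3))
        bands <- simulate_bands(geo, fields$spectral,
                                noise_sd = 0.005 * noise_scale,
                                seed = child_seed(sseed, 4))
      } else {
        frames <- NULL; bands <- NULL
      }
      set.seed(child_seed(sseed, 5))
      physio_raw <- make_raw_physio(p_max_t, rec_t, chl_t, noise_scale)

      sid <- sprintf("%s_r%02d", lab, rep_i)
      pppi_t <- pppi(p_max_t, rec_t, chl_t)
      risk <- cdri(pppi_t, rnat_true)
      samples[[sid]] <- list(sample_id = sid, treatment = lab,
                             frames = frames, bands = bands,
                             physio_raw = physio_raw,
                             profile = profiles[[di]])
      gt[[sid]] <- data.frame(
        sample_id = sid, treatment = lab, temp = sub("D[0-9]+$", "", lab),
        duration_days = des$duration_days, replicate = rep_i,
        "P_max" = p_max_t, "REC" = rec_t, "Chl_a+b" = chl_t,
        "PPPI" = pppi_t, "RNAT" = rnat_true, "CDRI" = risk$cdri,
        level = risk$level,
        sev_pmax = sev["pmax"], sev_rec = sev["rec"], sev_chl = sev["chl"],
        sev_dose = sev["dose"], check.names = FALSE)
    }
  }
  gt <- do.call(rbind, c(gt, list(make.row.names = FALSE)))
  structure(list(samples = samples, ground_truth = gt, profiles = profiles,
                 config = list(replicates = replicates, seed = seed,
                               noise_scale = noise_scale, shape = shape,
                               abnormal_frac = abnormal_frac)),
            class = "cold_dataset")
}

#' @export
print.cold_dataset <- function(x, ...) {
  cat(sprintf("cold_dataset: %d samples (%d designs x %d replicates), seed %d\n",
              length(x$samples), length(x$profiles), x$config$replicates,
              x$config$seed))
  invisible(x)
}
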