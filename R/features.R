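# The 16 spatial-variability feature parameters: 8 statistical operators on
# the raw value sequence and 8 structural (histogram / gradient / GLCM)
# operators on the min-max quantized values.

FEATURE_EPS <- 1e-10  # epsilon inside log2() terms

#' Statistical spatial-variability features
#'
#' Population-moment statistics of a value sequence (a transect profile or a
#' flattened region patch): mean `A`, population variance `VAR`, coefficient
#' of variation `COV = sigma/A * 100` (%), interquartile range `IQR`
#' (linear-interpolation quantiles), skewness `SKE`, excess kurtosis `KUR`,
#' inertia `INE = sum (x_i - x_(i-1))^2`, and the lag-1 normalized
#' autocorrelation `ACOR`. For a constant sequence `SKE`, `KUR`, `ACOR` and
#' `COV` are defined as 0.
#'
#' @param values Numeric vector, length >= 2 (pipeline supports are >= 8),
#'   all finite.
#' @return Named numeric vector of the 8 statistical features.
#' @examples
#' statistical_features(c(1, 2, 3, 4))
#' @export
statistical_features <- function(values) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2) cp_stop("statistical_features(): need length >= 2, got %d", n)
  if (any(!is.finite(x))) cp_stop("statistical_features(): non-finite values")
  a <- mean(x)
  v <- mean((x - a)^2)
  s <- sqrt(v)
  if (s > 0) {
    cov <- s / a * 100
    if (a == 0) {
      cov <- NaN
      cp_log("statistical_features: zero mean with nonzero sd, COV non-finite")
    }
    ske <- mean(((x - a) / s)^3)
    kur <- mean(((x - a) / s)^4) - 3
    acor <- sum((x[-n] - a) * (x[-1] - a)) / sum((x - a)^2)
  } else {
    cov <- 0; ske <- 0; kur <- 0; acor <- 0
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  c(A = a, VAR = v, COV = cov, IQR = q[2] - q[1], SKE = ske, KUR = kur,
    INE = sum(diff(x)^2), ACOR = acor)
}

#' Quantize values to integer gray levels
#'
#' Uniform min-max binning of the support's values into levels `0 .. L-1`.
#' A constant input maps entirely to level 0. The min maps to 0 and the max
#' to L-1 for any non-constant input.
#'
#' @param values Numeric vector or matrix, finite.
#' @param levels Number of gray levels L (default 16).
#' @return Integer vector/matrix of the same shape, values in `0 .. L-1`.
#' @export
quantize <- function(values, levels = 16L) {
  if (any(!is.finite(values))) cp_stop("quantize(): non-finite values")
  lo <- min(values); hi <- max(values)
  if (hi <= lo) {
    q <- values; q[] <- 0L; storage.mode(q) <- "integer"; return(q)
  }
  q <- floor((values - lo) / (hi - lo) * levels)
  q[q >= levels] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}

#' Stack a 1D profile into a square matrix
#'
#' Repeats the profile as identical rows to form an N x N matrix, so that
#' the GLCM texture operators defined on images can be applied to transect
#' profiles: a horizontal-offset GLCM of the stacked square equals the
#' co-occurrence distribution of adjacent profile pairs.
#'
#' @param profile A [leaf_profile] or numeric vector, length N >= 2.
#' @return N x N numeric matrix; every row is the profile.
#' @export
profile_to_square <- function(profile) {
  x <- if (inherits(profile, "leaf_profile")) profile$values else as.numeric(profile)
  n <- length(x)
  if (n < 2) cp_stop("profile_to_square(): need length >= 2, got %d", n)
  matrix(rep(x, each = n), nrow = n)
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized gray levels at a fixed pixel offset,
#' accumulated in both directions (symmetric) and normalized to total mass 1.
#' Pairs are only counted where both pixels are valid.
#'
#' @param mat Integer matrix of quantized levels (from [quantize()]); may
#'   contain NA for invalid pixels.
#' @param offset Integer displacement `c(drow, dcol)` (default `c(0, 1)`:
#'   horizontal neighbors).
#' @param levels Number of gray levels L (default 16).
#' @return An object of class `glcm_matrix`: list with `p` (L x L matrix
#'   summing to 1), `levels`, `offset`, `n_pairs`.
#' @export
glcm <- function(mat, offset = c(0L, 1L), levels = 16L) {
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1L)
  nr <- nrow(mat); nc <- ncol(mat)
  dr <- offset[1]; dc <- offset[2]
  r0 <- seq_len(nr - abs(dr)); c0 <- seq_len(nc - abs(dc))
  if (dr < 0) r0 <- r0 - dr
  if (dc < 0) c0 <- c0 - dc
  if (length(r0) == 0 || length(c0) == 0) cp_stop("glcm(): no valid pairs at offset")
  a <- mat[r0, c0, drop = FALSE]
  b <- mat[r0 + dr, c0 + dc, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) cp_stop("glcm(): no valid pairs at offset")
  counts <- matrix(0, levels, levels)
  tab <- table(factor(a[keep], levels = 0:(levels - 1L)),
               factor(b[keep], levels = 0:(levels - 1L)))
  counts <- counts + tab + t(tab)  # symmetrize
  p <- matrix(as.numeric(counts / sum(counts)), levels, levels)
  structure(list(p = p, levels = levels, offset = offset,
                 n_pairs = sum(keep)),
            class = "glcm_matrix")
}

#' Structural spatial-variability features
#'
#' Histogram, gradient and GLCM texture operators on the quantized support:
#' Shannon entropy `SENT` of the gray-level histogram; Laplace entropy
#' `LENT` of the absolute first-difference (gradient) distribution;
#' and the GLCM features contrast `CON`, angular second moment `ASM`,
#' texture entropy `TENT`, homogeneity `HOM`, inertia moment
#' `INEM = sum (i^2+j^2) P(i,j)` (levels indexed from 0), and small gradient
#' advantage `SGA` from the gray-level/gradient co-occurrence distribution.
#' For 1D supports the GLCM is taken on the [profile_to_square()] stack with
#' a horizontal offset, which is equivalent to co-occurrence of adjacent
#' profile values.
#'
#' @param values Numeric vector (1D support) or matrix with NAs outside the
#'   valid region (2D support).
#' @param levels Number of quantization levels (default 16).
#' @param offset GLCM offset (default horizontal `c(0, 1)`).
#' @return Named numeric vector of the 8 structural features.
#' @export
structural_features <- function(values, levels = 16L, offset = c(0L, 1L)) {
  is_2d <- is.matrix(values)
  vals <- if (is_2d) {
    tv <- t(values)          # row-major flatten, as for the statistical set
    tv[!is.na(tv)]
  } else as.numeric(values)
  if (length(vals) < 2) cp_stop("structural_features(): need >= 2 valid values")
  if (any(!is.finite(vals))) cp_stop("structural_features(): non-finite values")

  if (is_2d) {
    q <- values
    vmask <- !is.na(values)
    q[vmask] <- quantize(values[vmask], levels)  # elementwise, order-safe
    storage.mode(q) <- "integer"
    gmat <- glcm(q, offset = offset, levels = levels)
  } else {
    q1 <- quantize(vals, levels)
    q <- matrix(rep(q1, each = length(q1)), nrow = length(q1))  # stacked square
    gmat <- glcm(q, offset = offset, levels = levels)
  }
  # histogram entropy over quantized levels of the support itself
  qv <- if (is_2d) q[!is.na(q)] else quantize(vals, levels)
  p_i <- tabulate(qv + 1L, nbins = levels) / length(qv)
  sent <- -sum(p_i[p_i > 0] * log2(p_i[p_i > 0] + FEATURE_EPS))

  # gradient (first differences) distribution entropy
  g <- diff(vals)
  sg <- sum(abs(g))
  if (sg > 0) {
    p_g <- abs(g) / sg
    lent <- -sum(p_g[p_g > 0] * log2(p_g[p_g > 0] + FEATURE_EPS))
  } else {
    lent <- 0
  }

  c(SENT = sent, LENT = lent, glcm_features(gmat),
    SGA = sga_feature(qv, g, levels))
}

#' GLCM texture features
#'
#' Contrast, angular second moment, texture entropy, homogeneity and inertia
#' moment evaluated directly on a normalized co-occurrence matrix `P(i, j)`
#' with levels indexed from 0.
#'
#' @param g A `glcm_matrix` from [glcm()], or a plain normalized matrix.
#' @return Named numeric vector `CON`, `ASM`, `TENT`, `HOM`, `INEM`.
#' @export
glcm_features <- function(g) {
  P <- if (inherits(g, "glcm_matrix")) g$p else as.matrix(g)
  L <- nrow(P)
  I <- matrix(0:(L - 1L), L, L)  # row level i
  J <- t(I)                      # col level j
  c(CON  = sum((I - J)^2 * P),
    ASM  = sum(P^2),
    TENT = -sum(P[P > 0] * log2(P[P > 0] + FEATURE_EPS)),
    HOM  = sum(P / (1 + (I - J)^2)),
    INEM = sum((I^2 + J^2) * P))
}

# Small gradient advantage from the gray-level / gradient-level co-occurrence
# distribution H(i, j): T = [sum_ij H(i,j) / (j+1)^2] / sum_ij H(i,j), with the
# gradient magnitude |first difference| quantized to the same number of levels.
# Close to 1 when small gradients dominate (smooth support), smaller when
# large gradients are frequent.
#' @noRd
sga_feature <- function(qv, g, levels) {
  ga <- abs(g)
  gq <- quantize(ga, levels)                 # gradient level of each step
  # pair each gradient step with the gray level of its left pixel
  gl <- qv[seq_along(gq)]
  h <- table(gl, gq)
  sum(h / (as.numeric(colnames(h))[col(h)] + 1)^2) / sum(h)
}

#' Evaluate all 16 spatial-variability features on one support
#'
#' Statistical features operate on the value sequence (for a 2D region the
#' valid patch values flattened in row-major order, so the sequential
#' operators INE/ACOR follow the image scan order); structural features
#' operate on the quantized support.
#'
#' @param values Numeric vector (1D) or matrix with NAs (2D region).
#' @param levels,offset Quantization levels and GLCM offset.
#' @return Named numeric vector of 16 features in canonical order.
#' @export
spatial_features <- function(values, levels = 16L, offset = c(0L, 1L)) {
  vals <- if (is.matrix(values)) {
    tv <- t(values)          # row-major flatten
    tv[!is.na(tv)]
  } else values
  c(statistical_features(vals), structural_features(values, levels, offset))
}

#' Canonical feature-column names
#'
#' @return Character vector of the 624 "PARAM/DIM/FEATURE" names in
#'   deterministic order (parameter-major, then dimension, then feature).
#' @export
feature_names <- function() {
  unlist(lapply(ALL_PARAMS, function(p)
    lapply(ALL_DIMS, function(d)
      paste(p, d, ALL_FEATURES, sep = "/"))), use.names = FALSE)
}

#' Assemble the samples x 624 feature table for a synthetic experiment
#'
#' For every sample: computes the 13 phenotypic parameter maps, extracts the
#' three sampling supports from its leaf geometry, evaluates the 16 features
#' on each support, and appends the physiological targets and design
#' metadata. Samples with an uncomputable map are dropped with a log entry.
#'
#' @param dataset A `cold_dataset` from [build_dataset()].
#' @param levels,offset GLCM settings (defaults 16 levels, horizontal offset).
#' @return A data.frame: `sample_id`, `treatment`, `duration_days`,
#'   `replicate`, 624 feature columns, then `P_max`, `REC`, `Chl_a+b`,
#'   `PPPI`, `RNAT`, `CDRI`, `level`.
#' @export
build_feature_table <- function(dataset, levels = 16L, offset = c(0L, 1L)) {
  stopifnot(inherits(dataset, "cold_dataset"))
  fn <- feature_names()
  rows <- vector("list", length(dataset$samples))
  for (k in seq_along(dataset$samples)) {
    smp <- dataset$samples[[k]]
    row <- tryCatch(sample_features(smp, levels, offset),
                    error = function(e) {
                      cp_log("build_feature_table: dropping sample %s (%s)",
                             smp$sample_id, conditionMessage(e))
                      NULL
                    })
    rows[[k]] <- row
  }
  keep <- !vapply(rows, is.null, logical(1))
  feats <- do.call(rbind, rows[keep])
  colnames(feats) <- fn
  gt <- dataset$ground_truth[keep, , drop = FALSE]
  out <- cbind(gt[, c("sample_id", "treatment", "duration_days", "replicate")],
               as.data.frame(feats, check.names = FALSE),
               gt[, c("P_max", "REC", "Chl_a+b", "PPPI", "RNAT", "CDRI", "level")])
  rownames(out) <- NULL
  out
}

# All 16 x 13 x 3 features of one synthetic sample, in feature_names() order.
#' @noRd
sample_features <- function(smp, levels = 16L, offset = c(0L, 1L)) {
  maps <- sample_param_maps(smp)
  if (length(maps) != length(ALL_PARAMS))
    cp_stop("missing parameter maps (%d of %d)", length(maps), length(ALL_PARAMS))
  out <- numeric(0)
  for (p in ALL_PARAMS) {
    pm <- maps[[p]]
    geo <- smp$frames$geometry
    supports <- list(
      parallel_transect(pm, geo)$values,
      perpendicular_transect(pm, geo)$values,
      region_patch(pm, geo)$values)
    for (s in supports) out <- c(out, spatial_features(s, levels, offset))
  }
  if (any(!is.finite(out)))
    cp_stop("non-finite feature values")
  out
}
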