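# Independent brute-force oracles for the spatial-variability feature
# formulas and the evaluation metrics. Written as naive loops, deliberately
# sharing no code with the package implementation.

oracle_stats <- function(x) {
  n <- length(x)
  A <- sum(x) / n
  VAR <- sum((x - A)^2) / n
  sig <- sqrt(VAR)
  COV <- if (sig == 0) 0 else sig / A * 100
  q <- unname(stats::quantile(x, c(0.25, 0.75), type = 7))
  SKE <- if (sig == 0) 0 else sum(((x - A) / sig)^3) / n
  KUR <- if (sig == 0) 0 else sum(((x - A) / sig)^4) / n - 3
  INE <- 0
  for (i in 2:n) INE <- INE + (x[i] - x[i - 1])^2
  ACOR <- if (sig == 0) 0 else {
    num <- 0
    for (i in 1:(n - 1)) num <- num + (x[i] - A) * (x[i + 1] - A)
    num / sum((x - A)^2)
  }
  c(A = A, VAR = VAR, COV = COV, IQR = q[2] - q[1], SKE = SKE, KUR = KUR,
    INE = INE, ACOR = ACOR)
}

# min-max quantization, enumerated per element
oracle_quantize <- function(x, L) {
  lo <- min(x); hi <- max(x)
  q <- integer(length(x))
  if (hi > lo) {
    for (i in seq_along(x)) {
      q[i] <- floor((x[i] - lo) / (hi - lo) * L)
      if (q[i] >= L) q[i] <- L - 1L
    }
  }
  q
}

# symmetric normalized GLCM of an integer matrix by pair enumeration
oracle_glcm <- function(qm, L, dr = 0, dc = 1) {
  counts <- matrix(0, L, L)
  for (r in seq_len(nrow(qm))) {
    for (cc in seq_len(ncol(qm))) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nrow(qm) || c2 < 1 || c2 > ncol(qm)) next
      a <- qm[r, cc]; b <- qm[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
      counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
    }
  }
  counts / sum(counts)
}

oracle_struct <- function(values, L = 16L) {
  eps <- 1e-10
  is2d <- is.matrix(values)
  if (is2d) {
    seq_vals <- c()
    for (r in seq_len(nrow(values))) {
      for (cc in seq_len(ncol(values))) {
        v <- values[r, cc]
        if (!is.na(v)) seq_vals <- c(seq_vals, v)
      }
    }
  } else seq_vals <- values
  qseq <- oracle_quantize(seq_vals, L)

  SENT <- 0
  for (lev in 0:(L - 1)) {
    p <- sum(qseq == lev) / length(qseq)
    if (p > 0) SENT <- SENT - p * log2(p + eps)
  }
  g <- diff(seq_vals)
  LENT <- 0
  if (sum(abs(g)) > 0) {
    for (i in seq_along(g)) {
      p <- abs(g[i]) / sum(abs(g))
      if (p > 0) LENT <- LENT - p * log2(p + eps)
    }
  }
  if (is2d) {
    qm <- values
    qm[!is.na(values)] <- NA
    # quantize valid values in row-major order back into the matrix
    k <- 1
    for (r in seq_len(nrow(values))) {
      for (cc in seq_len(ncol(values))) {
        if (!is.na(values[r, cc])) { qm[r, cc] <- qseq[k]; k <- k + 1 }
      }
    }
  } else {
    # stacked square of the quantized profile
    n <- length(qseq)
    qm <- matrix(NA_integer_, n, n)
    for (r in seq_len(n)) for (cc in seq_len(n)) qm[r, cc] <- qseq[cc]
  }
  P <- oracle_glcm(qm, L)
  CON <- 0; ASM <- 0; TENT <- 0; HOM <- 0; INEM <- 0
  for (i in 0:(L - 1)) {
    for (j in 0:(L - 1)) {
      p <- P[i + 1, j + 1]
      ASM <- ASM + p^2
      CON <- CON + (i - j)^2 * p
      HOM <- HOM + p / (1 + (i - j)^2)
      INEM <- INEM + (i^2 + j^2) * p
      if (p > 0) TENT <- TENT - p * log2(p + eps)
    }
  }
  # gray-level / gradient-level co-occurrence, small-gradient weighting
  gq <- oracle_quantize(abs(g), L)
  num <- 0; den <- 0
  for (i in seq_along(gq)) {
    num <- num + 1 / (gq[i] + 1)^2
    den <- den + 1
  }
  SGA <- num / den
  c(SENT = SENT, LENT = LENT, CON = CON, ASM = ASM, TENT = TENT, HOM = HOM,
    INEM = INEM, SGA = SGA)
}

oracle_all16 <- function(values, L = 16L) {
  if (is.matrix(values)) {
    seq_vals <- c()
    for (r in seq_len(nrow(values)))
      for (cc in seq_len(ncol(values)))
        if (!is.na(values[r, cc])) seq_vals <- c(seq_vals, values[r, cc])
  } else seq_vals <- values
  c(oracle_stats(seq_vals), oracle_struct(values, L))
}

# classification metrics by direct contingency enumeration
oracle_classification <- function(y_true, y_pred, classes) {
  n <- length(y_true)
  correct <- 0
  for (i in seq_len(n)) if (y_true[i] == y_pred[i]) correct <- correct + 1
  po <- correct / n
  pe <- 0
  for (cl in classes) {
    a <- sum(y_true == cl); b <- sum(y_pred == cl)
    pe <- pe + a * b / n^2
  }
  list(acc = po * 100, kappa = (po - pe) / (1 - pe))
}

# small noise-free dataset shared across tests (lazily built once)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_dataset(replicates = 1L, seed = 7L, noise_scale = 0,
                              abnormal_frac = 0)
    cache
  }
})
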