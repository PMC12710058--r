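#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a consistent error class
#' @noRd
cp_stop <- function(msg, ..., class = "coldpheno_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Structured log line to stderr
#' @noRd
cp_log <- function(fmt, ...) {
  message(sprintf("[coldpheno] %s", sprintf(fmt, ...)))
}

#' Derive a child seed from a base seed (kept below 2^31)
#' @noRd
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 9973) %% 2147483629)
}

#' Deterministic string hash (FNV-1a, 32-bit) for config caching
#' @noRd
cp_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648 - (h >= 2147483648) * 0), as.integer(b))
    h <- (as.double(h %% 4294967296) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Check a numeric scalar
#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
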