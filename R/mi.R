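# Mutual-information feature ranking and the key-feature selection rules.

#' Mutual information between two sample vectors (bits)
#'
#' Plug-in estimate on an equal-frequency discretization of both variables
#' (rank-based, deterministic tie splitting), log base 2. Equal-frequency
#' binning makes the estimate invariant under strictly monotone transforms
#' of either argument and symmetric in its arguments.
#'
#' @param x,y Numeric vectors of equal length (>= 20).
#' @param bins Number of bins per variable; default
#'   `max(4, floor(sqrt(n/5)))`.
#' @return MI estimate in bits (>= 0). A constant input gives 0 with a
#'   warning.
#' @export
mutual_information <- function(x, y, bins = NULL) {
  n <- length(x)
  if (length(y) != n || n < 20)
    cp_stop("mutual_information(): need equal lengths >= 20")
  bins <- bins %||% max(4L, floor(sqrt(n / 5)))
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("mutual_information(): constant vector, MI = 0")
    return(0)
  }
  bx <- equal_freq_bin(x, bins)
  by <- equal_freq_bin(y, bins)
  joint <- table(bx, by) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
  max(mi, 0)
}

#' @noRd
equal_freq_bin <- function(x, bins) {
  r <- rank(x, ties.method = "first")
  ceiling(r * bins / length(x))
}

#' Mutual-information table over all features and physiological targets
#'
#' @param feature_table Feature table from [build_feature_table()] (or any
#'   data.frame containing the 624 feature columns and the target columns).
#' @param targets Target column names (default `P_max`, `REC`, `Chl_a+b`).
#' @param bins Bins for [mutual_information()].
#' @return Numeric matrix features x targets of MI values (bits).
#' @export
mi_table <- function(feature_table, targets = PHYSIO_TARGETS, bins = NULL) {
  fn <- intersect(feature_names(), colnames(feature_table))
  if (length(fn) != length(feature_names()))
    cp_stop("mi_table(): feature table is missing %d feature columns",
            length(feature_names()) - length(fn))
  out <- matrix(NA_real_, length(fn), length(targets),
                dimnames = list(fn, targets))
  for (tg in targets) {
    yv <- feature_table[[tg]]
    for (f in fn) out[f, tg] <- mutual_information(feature_table[[f]], yv, bins)
  }
  out
}

#' Typical features: top-2 by MI per source, dimension and target
#'
#' For each combination of imaging source (chlorophyll fluorescence vs
#' spectral index), sampling dimension and physiological target, the two
#' features with the largest MI (ties broken lexicographically by feature
#' name).
#'
#' @param mi_tab Matrix from [mi_table()].
#' @return data.frame with columns `source`, `dim`, `target`, `rank`,
#'   `feature`, `mi` (2 x 3 x 3 cells of two rows each).
#' @export
rank_typical_features <- function(mi_tab) {
  check_mi_table(mi_tab)
  parsed <- parse_feature_names(rownames(mi_tab))
  dim_of <- parsed$dim
  src_of <- ifelse(parsed$param %in% FLUOR_PARAMS, "fluorescence", "spectral")
  rows <- list()
  for (src in c("fluorescence", "spectral")) {
    for (dm in ALL_DIMS) {
      sel <- src_of == src & dim_of == dm
      for (tg in colnames(mi_tab)) {
        sub_mi <- mi_tab[sel, tg]
        ord <- order(-sub_mi, names(sub_mi))
        top <- ord[1:2]
        rows[[length(rows) + 1L]] <- data.frame(
          source = src, dim = dm, target = tg, rank = 1:2,
          feature = names(sub_mi)[top], mi = unname(sub_mi[top]))
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Select the six key features
#'
#' Per physiological target, the two features with the highest MI overall.
#' When a feature would be claimed by more than one target, it is kept by
#' the target for which its MI is largest and the other target substitutes
#' its next-ranked unclaimed feature, so that six distinct features result
#' (two per target).
#'
#' @param mi_tab Matrix from [mi_table()].
#' @return data.frame `target`, `rank`, `feature`, `mi` (6 rows), ordered
#'   by target (P_max, REC, Chl) then rank.
#' @export
select_key_features <- function(mi_tab) {
  check_mi_table(mi_tab)
  targets <- colnames(mi_tab)
  if (length(unique(rownames(mi_tab))) < 6)
    cp_stop("select_key_features(): fewer than 6 distinct features available")
  ranks <- lapply(targets, function(tg) {
    ord <- order(-mi_tab[, tg], rownames(mi_tab))
    data.frame(feature = rownames(mi_tab)[ord], mi = mi_tab[ord, tg])
  })
  names(ranks) <- targets
  pos <- stats::setNames(rep(1L, length(targets)), targets)
  need <- stats::setNames(rep(2L, length(targets)), targets)
  claimed <- character(0)
  out <- list()
  while (any(need > 0)) {
    # current best unclaimed candidate of every target still in need
    cand <- list()
    for (tg in targets[need > 0]) {
      while (pos[tg] <= nrow(ranks[[tg]]) &&
             ranks[[tg]]$feature[pos[tg]] %in% claimed)
        pos[tg] <- pos[tg] + 1L
      if (pos[tg] > nrow(ranks[[tg]]))
        cp_stop("select_key_features(): fewer than 6 distinct features available")
      cand[[tg]] <- ranks[[tg]][pos[tg], ]
    }
    mis <- vapply(cand, `[[`, numeric(1), "mi")
    feats <- vapply(cand, `[[`, character(1), "feature")
    # highest-MI claim wins; ties broken by feature name then target order
    best <- names(cand)[order(-mis, feats)][1]
    out[[length(out) + 1L]] <- data.frame(
      target = best, rank = 3L - need[[best]], feature = feats[[best]],
      mi = mis[[best]])
    claimed <- c(claimed, feats[[best]])
    need[best] <- need[best] - 1L
    pos[best] <- pos[best] + 1L
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res <- res[order(match(res$target, targets), res$rank), ]
  rownames(res) <- NULL
  res
}

# Split "PARAM/DIM/FEATURE" names from the right (the parameter name itself
# may contain a slash, e.g. "Fv/Fm").
#' @noRd
parse_feature_names <- function(x) {
  feat <- sub("^.*/", "", x)
  rest <- sub("/[^/]*$", "", x)
  dm <- sub("^.*/", "", rest)
  list(param = sub("/[^/]*$", "", rest), dim = dm, feature = feat)
}

#' @noRd
check_mi_table <- function(mi_tab) {
  if (!is.matrix(mi_tab) || is.null(rownames(mi_tab)) || is.null(colnames(mi_tab)))
    cp_stop("expected an MI matrix with feature rownames and target colnames")
  if (any(!is.finite(mi_tab)) || any(mi_tab < 0))
    cp_stop("MI table must be complete and nonnegative")
}
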