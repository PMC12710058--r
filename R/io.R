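# Plain-text I/O: CSV rasters with a JSON manifest, CSV tables. (The
# deployment image has no TIFF library; CSV rasters keep every artifact
# human-readable and diffable.)

#' Write a raster to CSV
#'
#' @param values Numeric matrix (NA allowed).
#' @param path Output file path.
#' @export
write_raster_csv <- function(values, path) {
  utils::write.table(values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a raster from CSV
#' @param path CSV file written by [write_raster_csv()].
#' @return Numeric matrix.
#' @export
read_raster_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Export a synthetic dataset to a directory
#'
#' Writes, per sample, the five fluorescence frames and four band images as
#' CSV rasters plus the leaf mask; one temperature-profile CSV per design
#' (`hour`, `temp_c`); the ground truth as CSV; and a JSON manifest tying
#' everything together.
#'
#' @param dataset A `cold_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest (invisibly).
#' @export
export_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cold_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_samples = length(dataset$samples),
                   config = dataset$config, samples = list())
  for (sid in names(dataset$samples)) {
    smp <- dataset$samples[[sid]]
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    frames <- smp$frames[c("fo", "fm", "fo_p", "fm_p", "fs")]
    for (nm in names(frames))
      write_raster_csv(frames[[nm]], file.path(sdir, paste0(nm, ".csv")))
    for (nm in c("blue", "green", "red", "nir"))
      write_raster_csv(smp$bands[[nm]], file.path(sdir, paste0(nm, ".csv")))
    write_raster_csv(smp$frames$geometry$mask * 1L, file.path(sdir, "mask.csv"))
    manifest$samples[[sid]] <- list(
      dir = sid, treatment = smp$treatment,
      frames = paste0(c("fo", "fm", "fo_p", "fm_p", "fs"), ".csv"),
      bands = paste0(c("blue", "green", "red", "nir"), ".csv"))
  }
  for (lab in names(dataset$profiles)) {
    pr <- dataset$profiles[[lab]]
    utils::write.csv(
      data.frame(hour = seq_along(pr$hourly_c) - 1L, temp_c = pr$hourly_c),
      file.path(dir, paste0("temperature_", lab, ".csv")), row.names = FALSE)
  }
  utils::write.csv(dataset$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Export a transect profile or region patch as CSV
#'
#' Columns `index`, `row`, `col`, `value` (0-based pixel coordinates).
#'
#' @param x A `leaf_profile` or `region_patch`.
#' @param path Output file path.
#' @export
export_support_csv <- function(x, path) {
  if (inherits(x, "leaf_profile")) {
    df <- data.frame(index = seq_along(x$values) - 1L,
                     row = x$pixel_coords[, "row"],
                     col = x$pixel_coords[, "col"], value = x$values)
  } else if (inherits(x, "region_patch")) {
    idx <- which(!is.na(x$values), arr.ind = TRUE)
    df <- data.frame(index = seq_len(nrow(idx)) - 1L,
                     row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                     value = x$values[idx])
  } else cp_stop("export_support_csv(): unsupported object")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
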