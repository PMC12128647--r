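# Standard-format I/O: traces, features and fertility tables as CSV
# (comma-separated, UTF-8, header row, '.' decimal), images as
# single-channel TIFF. All readers validate their schema and report
# offending rows by line number.

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, ": missing required columns: ",
         paste(missing, collapse = ", "))
  }
}

#' Write perimeter traces to CSV
#'
#' Long format: one row per vertex with columns `ram_id`, `object_label`,
#' `vertex_index`, `x_um`, `y_um` (closing vertex omitted; traces are closed
#' by convention).
#'
#' @param traces List of [perimeter_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    n <- length(tr$x) - 1L
    data.frame(ram_id = tr$ram_id, object_label = tr$label,
               vertex_index = seq_len(n), x_um = tr$x[seq_len(n)],
               y_um = tr$y[seq_len(n)], stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read perimeter traces from CSV
#'
#' @param path CSV path in the [write_traces()] schema.
#' @return List of [perimeter_trace()] objects.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("ram_id", "object_label", "vertex_index",
                         "x_um", "y_um"), "read_traces")
  bad <- which(!is.finite(df$x_um) | !is.finite(df$y_um))
  if (length(bad)) {
    stop("read_traces: non-numeric coordinates at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  keys <- interaction(df$ram_id, df$object_label, drop = TRUE)
  lapply(split(df, keys), function(d) {
    d <- d[order(d$vertex_index), ]
    if (nrow(d) < 8) {
      stop("read_traces: trace ", d$ram_id[1], "/", d$object_label[1],
           " has fewer than 8 vertices")
    }
    perimeter_trace(d$x_um, d$y_um, ram_id = d$ram_id[1],
                    label = d$object_label[1])
  })
}

#' Write a per-ram feature table to CSV
#' @param features Data frame (e.g. from [summarize_ram()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-ram feature table from CSV
#'
#' @param path CSV path with a `ram_id` column and numeric feature columns.
#' @return Data frame.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, "ram_id", "read_features")
  num <- vapply(df, is.numeric, logical(1))
  bad_rows <- which(apply(is.na(df[num]), 1, any))
  if (length(bad_rows)) {
    stop("read_features: missing/invalid numeric values at line(s) ",
         paste(utils::head(bad_rows + 1L, 5), collapse = ", "))
  }
  if (!is.null(df$area_um2) && any(df$area_um2 <= 0)) {
    stop("read_features: nonpositive area at line(s) ",
         paste(which(df$area_um2 <= 0) + 1L, collapse = ", "))
  }
  df
}

#' Read per-ram fertility records from CSV
#'
#' @param path CSV with columns `ram_id` and `conception_rate` (percent).
#' @return Data frame.
#' @export
read_fertility <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("ram_id", "conception_rate"), "read_fertility")
  bad <- which(!is.finite(df$conception_rate) | df$conception_rate < 0 |
                 df$conception_rate > 100)
  if (length(bad)) {
    stop("read_fertility: conception_rate out of [0, 100] at line(s) ",
         paste(bad + 1L, collapse = ", "))
  }
  df
}

#' Write per-ram fertility records to CSV
#' @param fertility Data frame with `ram_id` and `conception_rate`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fertility <- function(fertility, path) {
  utils::write.csv(fertility, path, row.names = FALSE)
  invisible(path)
}

#' Write a grayscale matrix as a single-channel TIFF
#'
#' @param image Numeric matrix in gray levels.
#' @param path Output path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, bit_depth = 8) {
  stopifnot(bit_depth %in% c(8, 16))
  scaled <- pmin(pmax(image / (2^bit_depth - 1), 0), 1)
  tiff::writeTIFF(scaled, path, bits.per.sample = bit_depth)
  invisible(path)
}

#' Read a single-channel TIFF as a gray-level matrix
#'
#' @param path TIFF path.
#' @param bit_depth Bit depth used to rescale to gray levels.
#' @return Numeric matrix.
#' @export
read_image_tiff <- function(path, bit_depth = 8) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * (2^bit_depth - 1)
}

#' Write a synthetic field to disk
#'
#' Fluorescence and phase images as single-channel TIFF, the label image as
#' 16-bit TIFF, and the ground truth as CSV.
#'
#' @param field A `synthetic_field` from [generate_field()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param bit_depth Bit depth of the intensity images.
#' @return Named vector of file paths, invisibly.
#' @export
write_field <- function(field, dir, prefix = "field", bit_depth = 8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(fluorescence = file.path(dir, paste0(prefix, "_fluor.tif")),
         phase = file.path(dir, paste0(prefix, "_phase.tif")),
         labels = file.path(dir, paste0(prefix, "_labels.tif")),
         truth = file.path(dir, paste0(prefix, "_truth.csv")))
  write_image_tiff(field$fluorescence, p["fluorescence"], bit_depth)
  write_image_tiff(field$phase, p["phase"], bit_depth)
  tiff::writeTIFF(field$labels / 65535, p["labels"], bits.per.sample = 16)
  utils::write.csv(field$truth, p["truth"], row.names = FALSE)
  invisible(p)
}
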