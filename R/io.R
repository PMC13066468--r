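# Readers and writers for the dataset's file formats and the pipeline's
# intermediate tables. All coordinates are cm in track tables and px in
# detection/centroid tables; missing values serialize as empty cells; all
# writers are deterministic.

TRACK_COLS <- c("frame", "fish",
                "head_x", "head_y", "head_z",
                "pec_x", "pec_y", "pec_z",
                "tail_x", "tail_y", "tail_z",
                "flags")

#' Per-fish, per-frame 3D track table
#'
#' Validates and classes a data frame of 3D skeleton time series: one row per
#' frame per fish, columns `frame, fish, head_x..tail_z, flags` (extra
#' columns are preserved as-is). `flags` holds `;`-separated QC flag tokens.
#'
#' @param df A data frame with the track columns.
#' @return The validated `track_table` (a classed data frame).
#' @export
track_table <- function(df) {
  miss <- setdiff(TRACK_COLS, names(df))
  if (length(miss)) {
    stop("track table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  fish <- sort(unique(df$fish))
  if (length(fish) > 2) {
    stop("track table must contain at most two fish ids, got: ",
         paste(fish, collapse = ", "), call. = FALSE)
  }
  for (f in fish) {
    fr <- df$frame[df$fish == f]
    bad <- which(diff(fr) <= 0)
    if (length(bad)) {
      stop(sprintf("frame indices not strictly increasing for fish %s at row %d",
                   f, which(df$fish == f)[bad[1] + 1]), call. = FALSE)
    }
  }
  df$flags[is.na(df$flags)] <- ""
  class(df) <- c("track_table", "data.frame")
  df
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("<track_table> %d frames x %d fish (%d rows)\n",
              length(unique(x$frame)), length(unique(x$fish)), nrow(x)))
  NextMethod()
}

#' Write / read a track table as CSV
#'
#' Missing coordinates are written as empty cells; the round trip is lossless
#' (including missingness and flags). `read_tracks_csv` accepts a
#' `column_map` so externally produced CSVs with different headers can be
#' adapted without code changes; unknown extra columns are preserved.
#'
#' @param tracks A [track_table()].
#' @param path File path.
#' @param column_map Optional named character vector mapping file column
#'   names to the native names (e.g. `c(t = "frame")` renames `t`).
#' @return The track table (reader) or `path`, invisibly (writer).
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(df))
    names(df)[idx[!is.na(idx)]] <- column_map[!is.na(idx)]
  }
  miss <- setdiff(TRACK_COLS, names(df))
  if (length(miss)) {
    stop("malformed track CSV header; missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"flags" %in% names(df)) df$flags <- ""
  df$flags <- as.character(df$flags)
  df$flags[is.na(df$flags)] <- ""
  track_table(df)
}

#' Read experiment metadata
#'
#' Expects columns `experiment_id, date, sex, cage_type, genotype` with
#' `cage_type` in `circular`/`square` and `genotype` in `WT`/`mecp2`/
#' `fgfr1a`. An empty file yields an empty table.
#'
#' @param path File path to `metadata.csv`.
#' @return A data frame of validated records (possibly zero rows).
#' @export
read_metadata_csv <- function(path) {
  cols <- c("experiment_id", "date", "sex", "cage_type", "genotype")
  empty <- stats::setNames(
    data.frame(character(0), character(0), character(0), character(0), character(0)),
    cols
  )
  if (file.size(path) == 0) return(empty)
  df <- utils::read.csv(path, colClasses = "character")
  if (nrow(df) == 0) return(empty)
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("metadata CSV missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in cols) {
    bad <- which(is.na(df[[col]]) | df[[col]] == "")
    if (length(bad)) stop(sprintf("metadata row %d: empty %s", bad[1], col), call. = FALSE)
  }
  bad <- which(!df$cage_type %in% c("circular", "square"))
  if (length(bad)) {
    stop(sprintf("metadata row %d: unknown cage_type '%s'", bad[1], df$cage_type[bad[1]]), call. = FALSE)
  }
  bad <- which(!df$genotype %in% c("WT", "mecp2", "fgfr1a"))
  if (length(bad)) {
    stop(sprintf("metadata row %d: unknown genotype '%s'", bad[1], df$genotype[bad[1]]), call. = FALSE)
  }
  df[, c(cols, setdiff(names(df), cols))]
}

DET_COLS <- c("frame", "view", "det",
              "head_u", "head_v", "pec_u", "pec_v", "tail_u", "tail_v")

#' Write / read 2D detection tables
#'
#' Schema: `frame, view, det, head_u, head_v, pec_u, pec_v, tail_u, tail_v`
#' (one row per detected skeleton per view per frame; missing body points are
#' empty cells). This doubles as the reader for converted pose-estimator
#' exports.
#'
#' @param detections Detection data frame in the schema above.
#' @param path File path.
#' @export
write_detections_csv <- function(detections, path) {
  utils::write.csv(detections[, DET_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(DET_COLS, names(df))
  if (length(miss)) stop("detection CSV missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!df$view %in% VIEWS)
  if (length(bad)) stop(sprintf("detection row %d: unknown view '%s'", bad[1], df$view[bad[1]]), call. = FALSE)
  df
}

#' Write / read top-view identity centroid tables
#'
#' Schema: `frame, identity, u, v` (one row per identified centroid per
#' frame), as produced by whole-video identity tracking on the top camera.
#'
#' @param centroids Centroid data frame in the schema above.
#' @param path File path.
#' @export
write_centroids_csv <- function(centroids, path) {
  utils::write.csv(centroids[, c("frame", "identity", "u", "v")], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_centroids_csv
#' @export
read_centroids_csv <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("frame", "identity", "u", "v"), names(df))
  if (length(miss)) stop("centroid CSV missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df
}
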