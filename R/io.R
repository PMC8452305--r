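## Readers and writers for the plain-text interchange formats:
##  - event table: one row per detected event (time_s, amplitude,
##    spikelet_count), tab- or comma-delimited, delimiter auto-detected
##    from the header line;
##  - cell metadata: a Debian-control-format document with keys cell_id,
##    recording_duration_s, group_label, genotype;
##  - feature table: one row per cell with a fixed column contract.

EVENT_COLUMNS <- c("time_s", "amplitude", "spikelet_count")

FEATURE_COLUMNS <- c("cell_id", "group_label", "frequency_hz",
                     "frequency_mode_hz", "cv", "cv2", "pause_percent",
                     "rhythmicity_index", "cs_frequency_hz",
                     "doublet_frequency_hz", "combined_cs_frequency_hz",
                     "heterogeneous_cs")

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop_parse(paste0(path, ": empty file"))
  if (grepl("\t", header)) "\t" else ","
}

#' Read an event table
#'
#' @param path Path to a delimited text file with header columns
#'   `time_s`, `amplitude`, `spikelet_count` (tab or comma separated;
#'   detected from the header line).
#' @return A data.frame with the three event columns.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("event file not found: ", path))
  sep <- detect_delim(path)
  df <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, colClasses = "character",
               check.names = FALSE, strip.white = TRUE),
    error = function(e) stop_parse(paste0(path, ": ", conditionMessage(e))))
  if (!all(EVENT_COLUMNS %in% names(df)))
    stop_parse(paste0(path, ": header must contain columns ",
                      paste(EVENT_COLUMNS, collapse = ", ")))
  df <- df[EVENT_COLUMNS]
  out <- data.frame(time_s = suppressWarnings(as.numeric(df$time_s)),
                    amplitude = suppressWarnings(as.numeric(df$amplitude)),
                    spikelet_count = suppressWarnings(as.integer(df$spikelet_count)))
  bad <- which(!stats::complete.cases(out))
  if (length(bad))
    stop_parse(sprintf("%s: malformed row at line %d (data line %d)",
                       path, bad[1L] + 1L, bad[1L]))
  out
}

#' Read per-cell metadata
#'
#' @param path Path to a metadata document in `key: value` (DCF) format
#'   with keys `cell_id`, `recording_duration_s`, `group_label`,
#'   `genotype`. A missing or empty `recording_duration_s` is returned as
#'   `NA` and resolved by [spike_series()] (spike-span fallback with a
#'   warning).
#' @return A named list.
#' @export
read_cell_metadata <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("metadata file not found: ", path))
  m <- tryCatch(read.dcf(path), error = function(e)
    stop_parse(paste0(path, ": ", conditionMessage(e))))
  m <- as.list(m[1L, , drop = TRUE])
  dur <- if (is.null(m$recording_duration_s) || !nzchar(m$recording_duration_s)) NA_real_
         else suppressWarnings(as.numeric(m$recording_duration_s))
  if (!is.null(m$recording_duration_s) && nzchar(m$recording_duration_s) && is.na(dur))
    stop_parse(paste0(path, ": recording_duration_s is not numeric"))
  list(cell_id = m$cell_id %||% basename(path),
       recording_duration_s = dur,
       group_label = m$group_label %||% "unknown",
       genotype = m$genotype %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a validated spike event series from disk
#'
#' @param path Event-table file (see [read_event_table()]).
#' @param metadata_path Metadata file (see [read_cell_metadata()]).
#' @return A validated [spike_series()].
#' @export
load_event_series <- function(path, metadata_path) {
  ev <- read_event_table(path)
  md <- read_cell_metadata(metadata_path)
  spike_series(ev$time_s, recording_duration_s = md$recording_duration_s,
               amplitudes = ev$amplitude, spikelet_counts = ev$spikelet_count,
               cell_id = md$cell_id, group_label = md$group_label,
               genotype = md$genotype)
}

#' Write a spike event series to disk
#'
#' Times are serialized at microsecond precision (9 decimal places), so a
#' save/load round trip reproduces the decimal representation exactly.
#'
#' @param series A `spike_series`.
#' @param path Output event-table path (tab-delimited).
#' @param metadata_path Output metadata path; omit to skip.
#' @return `path`, invisibly.
#' @export
write_event_series <- function(series, path, metadata_path = NULL) {
  df <- data.frame(time_s = sprintf("%.9f", series$times),
                   amplitude = sprintf("%.6f", series$amplitudes),
                   spikelet_count = series$spikelet_counts)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    m <- matrix(c(series$cell_id, sprintf("%.6f", series$recording_duration_s),
                  series$group_label, series$genotype), nrow = 1)
    colnames(m) <- c("cell_id", "recording_duration_s", "group_label", "genotype")
    write.dcf(m, metadata_path)
  }
  invisible(path)
}

#' Write the per-cell feature table
#'
#' Column order and names follow a fixed contract so downstream tools can
#' rely on them; `heterogeneous_cs` is serialized as 0/1.
#'
#' @param features A data.frame with the columns of the feature contract
#'   (see [extract_features()]).
#' @param path Output path (tab-delimited text).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  missing_cols <- setdiff(FEATURE_COLUMNS, names(features))
  if (length(missing_cols))
    stop_validation(paste0("feature table is missing columns: ",
                           paste(missing_cols, collapse = ", ")))
  df <- features[FEATURE_COLUMNS]
  df$heterogeneous_cs <- as.integer(df$heterogeneous_cs)
  num <- setdiff(FEATURE_COLUMNS, c("cell_id", "group_label", "heterogeneous_cs"))
  for (cn in num) df[[cn]] <- sprintf("%.10g", df[[cn]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path Path to the table.
#' @return A data.frame with numeric feature columns and a logical
#'   `heterogeneous_cs`.
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  missing_cols <- setdiff(FEATURE_COLUMNS, names(df))
  if (length(missing_cols))
    stop_parse(paste0(path, ": missing columns: ",
                      paste(missing_cols, collapse = ", ")))
  df$heterogeneous_cs <- as.logical(df$heterogeneous_cs)
  df
}
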