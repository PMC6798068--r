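# Readers and writers for the pipeline's on-disk formats: internal
# (raw float64 array + JSON sidecar + events TSV), EDF+ with annotations,
# and the CSV feature/result tables.

#' Write an event table as TSV
#'
#' Columns `trial`, `sample`, `type`, `condition`; rows sorted by sample.
#'
#' @param events Event data frame (see [eeg_recording()]).
#' @param path Output file.
#' @export
write_events_tsv <- function(events, path) {
  ev <- events[order(events$sample), c("trial", "sample", "type", "condition")]
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event table from TSV
#'
#' @param path TSV file with header `trial sample type condition`.
#' @return Event data frame sorted by sample.
#' @export
read_events_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty events file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("trial", "sample", "type", "condition")
  if (!identical(header, need))
    stop("events TSV must have header: ", paste(need, collapse = "\t"))
  if (length(lines) == 1) return(empty_events()[, need])
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 4 || is.na(suppressWarnings(as.integer(p[2]))))
      stop("malformed events TSV row at line ", i + 1, ": ", lines[i + 1])
    if (!p[3] %in% event_types())
      stop("unknown event type at line ", i + 1, ": ", p[3])
  }
  ev <- data.frame(trial = as.integer(vapply(parts, `[`, "", 1)),
                   sample = as.integer(vapply(parts, `[`, "", 2)),
                   type = vapply(parts, `[`, "", 3),
                   condition = vapply(parts, `[`, "", 4),
                   stringsAsFactors = FALSE)
  ev[order(ev$sample), ]
}

#' Write a recording to disk
#'
#' `format = "internal"` writes `<path>.dat` (raw little-endian float64,
#' channel-major), `<path>.json` (sampling rate, channel labels, metadata)
#' and `<path>_events.tsv`. `format = "edf"` writes a single EDF+ file with
#' 16-bit samples and the events as EDF+ annotations; the physical range is
#' chosen to cover the observed amplitudes (error on non-finite input,
#' never silent clipping).
#'
#' @param recording An [eeg_recording()].
#' @param path Output path (without extension for the internal format).
#' @param format `"internal"` or `"edf"`.
#' @export
write_recording <- function(recording, path, format = c("internal", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(write_edf(recording, path))
  con <- file(paste0(path, ".dat"), "wb")
  writeBin(as.vector(t(recording$data)), con, size = 8, endian = "little")
  close(con)
  meta <- list(fs = recording$fs, channels = recording$channels,
               n_samples = ncol(recording$data),
               participant_id = recording$participant_id,
               group = recording$group,
               metadata = recording$metadata[setdiff(names(recording$metadata),
                                                     "filter")])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write_events_tsv(recording$events, paste0(path, "_events.tsv"))
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path Path as given to [write_recording()] (internal: without
#'   extension; edf: the `.edf` file).
#' @param format `"internal"` or `"edf"`.
#' @param label_map Named character vector mapping foreign annotation
#'   labels to the package's event types (EDF only). Annotations the map
#'   does not cover are dropped with a warning, or raise an error under
#'   `strict = TRUE`.
#' @param strict Error on unmapped annotation labels.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("internal", "edf"),
                           label_map = NULL, strict = FALSE) {
  format <- match.arg(format)
  if (format == "edf") return(read_edf(path, label_map, strict))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".dat"), "rb")
  x <- readBin(con, numeric(), n = meta$n_samples * length(meta$channels),
               size = 8, endian = "little")
  close(con)
  data <- t(matrix(x, nrow = meta$n_samples))
  events <- read_events_tsv(paste0(path, "_events.tsv"))
  if (!nrow(events)) warning("recording has no events")
  eeg_recording(data, meta$fs, meta$channels, events,
                participant_id = meta$participant_id %||% NA_character_,
                group = meta$group %||% NA_character_,
                metadata = as.list(meta$metadata))
}

#' Write the long feature table as CSV
#'
#' One row per (participant, context, location, feature).
#'
#' @param table Feature data frame.
#' @param path Output file.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV file.
#' @return Feature data frame.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the comparison results as CSV
#'
#' One row per (family, feature, location) with t, df, raw and
#' Holm-adjusted p, both group/condition means and the reject flag.
#'
#' @param results An `eeg_comparisons` data frame.
#' @param path Output file.
#' @export
write_results_table <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
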