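#' Construct a continuous EEG recording object
#'
#' The in-memory representation of a continuous recording: a channels x
#' samples matrix in microvolts, its sampling rate, ordered channel labels,
#' and an event stream. Sample indices are 0-based throughout the package;
#' the time of sample `s` is `s / fs` seconds.
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel labels, one per row.
#' @param events Data frame with columns `sample` (0-based integer), `type`
#'   (one of fixation_on, stimulus_on, button1, button2, trial_end),
#'   `trial` (integer) and `condition` (`"c1"`, `"c2"` or `NA`).
#' @param participant_id Identifier string.
#' @param group Participant group (`"FD"`, `"FI"`, `"FN"` or `NA`).
#' @param metadata List of free-form metadata (reference and ground labels
#'   by default).
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels, events = empty_events(),
                          participant_id = NA_character_, group = NA_character_,
                          metadata = list(reference = "FCz", ground = "Fpz")) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (fs <= 0) stop("fs must be > 0")
  if (nrow(data) != length(channels))
    stop("data row count (", nrow(data), ") must equal number of channel labels (",
         length(channels), ")")
  events <- validate_events(events, ncol(data))
  structure(list(data = data, fs = fs, channels = channels, events = events,
                 participant_id = participant_id, group = group,
                 metadata = metadata),
            class = "eeg_recording")
}

event_types <- function() {
  c("fixation_on", "stimulus_on", "button1", "button2", "trial_end")
}

empty_events <- function() {
  data.frame(sample = integer(), type = character(), trial = integer(),
             condition = character(), stringsAsFactors = FALSE)
}

validate_events <- function(events, n_samples = NULL) {
  need <- c("sample", "type", "trial", "condition")
  if (!all(need %in% names(events)))
    stop("events must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(events$type), event_types())
  if (length(bad))
    stop("unknown event type(s): ", paste(bad, collapse = ", "))
  if (nrow(events) && !is.null(n_samples) &&
      (min(events$sample) < 0 || max(events$sample) >= n_samples))
    stop("event sample indices must lie in [0, n_samples)")
  events[order(events$sample), , drop = FALSE]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.na(x$participant_id))
    cat(sprintf("  participant %s (%s)\n", x$participant_id, x$group))
  cat(sprintf("  events: %d (%s)\n", nrow(x$events),
              paste(sprintf("%s=%d", names(table(x$events$type)),
                            as.integer(table(x$events$type))), collapse = ", ")))
  invisible(x)
}
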