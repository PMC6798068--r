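# Minimal EDF+ (continuous) writer/reader: 16-bit samples, 1-second data
# records, one annotations channel carrying the event stream as time-stamped
# annotation lists (TALs). Covers exactly what the pipeline needs; not a
# general-purpose EDF library.

edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

edf_event_text <- function(ev) {
  sprintf("%s trial=%d cond=%s", ev$type, ev$trial,
          ifelse(is.na(ev$condition), "NA", ev$condition))
}

write_edf <- function(recording, path) {
  data <- recording$data
  if (any(!is.finite(data)))
    stop("recording contains non-finite amplitudes; not representable in EDF")
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  nch <- nrow(data); n <- ncol(data)
  n_rec <- ceiling(n / fs)
  pm <- max(1, ceiling(max(abs(data)) * 1.001))
  if (pm > 1e6)
    stop("amplitude range ", pm, " uV exceeds the representable range")
  dig_max <- 32767; dig_min <- -32767   # symmetric so 0 uV is exact

  # annotation TALs per record
  ev <- recording$events
  tals <- vapply(seq_len(n_rec) - 1, function(r) {
    tal <- sprintf("+%d\x14\x14", r)
    sel <- which(ev$sample >= r * fs & ev$sample < (r + 1) * fs)
    if (length(sel)) {
      onset <- ev$sample[sel] / fs
      tal <- paste0(tal, paste0(sprintf("+%.4f\x14", onset),
                                edf_event_text(ev[sel, , drop = FALSE]),
                                "\x14", collapse = ""))
    }
    tal
  }, character(1))
  ann_bytes <- max(32, max(nchar(tals, type = "bytes")) + 2)
  if (ann_bytes %% 2 == 1) ann_bytes <- ann_bytes + 1
  ann_spr <- ann_bytes / 2

  ns <- nch + 1
  header_bytes <- 256 * (1 + ns)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(edf_pad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(paste0("X X X ", recording$participant_id %||% "X"), 80)
  wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(header_bytes), 8)
  wr("EDF+C", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)
  wr(as.character(ns), 4)
  labels <- c(recording$channels, "EDF Annotations")
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr(if (i <= nch) "AgAgCl electrode" else "", 80)
  for (i in seq_len(ns)) wr(if (i <= nch) "uV" else "", 8)
  for (i in seq_len(ns)) wr(if (i <= nch) as.character(-pm) else "-1", 8)
  for (i in seq_len(ns)) wr(if (i <= nch) as.character(pm) else "1", 8)
  for (i in seq_len(ns)) wr(as.character(dig_min), 8)
  for (i in seq_len(ns)) wr(as.character(dig_max), 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(if (i <= nch) fs else ann_spr), 8)
  wr(sprintf("NS=%d", n), 32)          # true sample count (padding marker)
  for (i in seq_len(ns - 1)) wr("", 32)

  scale <- (dig_max - dig_min) / (2 * pm)
  for (r in seq_len(n_rec) - 1) {
    i0 <- r * fs + 1; i1 <- min(n, (r + 1) * fs)
    block <- matrix(0, nch, fs)
    block[, seq_len(i1 - i0 + 1)] <- data[, i0:i1, drop = FALSE]
    dig <- round((block + pm) * scale) + dig_min
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
    tal <- tals[r + 1]
    raw_tal <- c(charToRaw(tal), as.raw(rep(0, ann_bytes - nchar(tal, type = "bytes"))))
    writeBin(raw_tal, con)
  }
  invisible(path)
}

read_edf <- function(path, label_map = NULL, strict = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    out <- readChar(con, width, useBytes = TRUE)
    if (nchar(out, type = "bytes") < width) stop("unreadable EDF header: ", path)
    trimws(out)
  }
  rd(8)                                    # version
  patient <- rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(header_bytes) || is.na(n_rec) || is.na(ns) || ns < 1)
    stop("unreadable EDF header: ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)             # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  reserved <- vapply(seq_len(ns), function(i) rd(32), character(1))

  ann_i <- which(labels == "EDF Annotations")
  sig_i <- setdiff(seq_len(ns), ann_i)
  fs <- spr[sig_i[1]] / rec_dur
  data <- matrix(0, length(sig_i), n_rec * spr[sig_i[1]])
  ann_text <- character(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (i %in% ann_i) {
        raw <- readBin(con, "raw", n = spr[i] * 2)
        ann_text <- c(ann_text, rawToChar(raw[raw != as.raw(0)]))
      } else {
        dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
        j <- match(i, sig_i)
        phys <- (dig - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i]) +
          pmin_[i]
        data[j, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
      }
    }
  }
  m <- regmatches(reserved[1], regexec("NS=([0-9]+)", reserved[1]))[[1]]
  if (length(m) == 2) data <- data[, seq_len(as.integer(m[2])), drop = FALSE]

  events <- parse_edf_annotations(paste(ann_text, collapse = ""), fs,
                                  label_map, strict)
  if (!nrow(events)) warning("EDF file contains no mapped events")
  pid <- utils::tail(strsplit(patient, " ")[[1]], 1)
  eeg_recording(data, fs, labels[sig_i], events,
                participant_id = if (identical(pid, "X")) NA_character_ else pid)
}

parse_edf_annotations <- function(text, fs, label_map, strict) {
  # Walk \x14-separated tokens: a token of the form +<number>[\x15<dur>]
  # starts an annotation; following non-empty tokens (until the next onset
  # token) are its texts. Record keep-alive stamps carry no text.
  tokens <- strsplit(text, "\x14", fixed = TRUE)[[1]]
  rows <- list()
  onset <- NA_real_
  for (tok in tokens) {
    if (grepl("^[+-][0-9.]+(\x15[0-9.]*)?$", tok)) {
      onset <- as.numeric(sub("\x15.*$", "", tok))
      next
    }
    if (!nzchar(tok) || is.na(onset)) next
    w <- strsplit(tok, " ", fixed = TRUE)[[1]]
    type <- w[1]
    if (!is.null(label_map) && type %in% names(label_map))
      type <- label_map[[type]]
    if (!type %in% event_types()) {
      if (strict) stop("unknown annotation label: '", w[1], "'")
      warning("dropping unmapped annotation label: '", w[1], "'")
      next
    }
    trial <- suppressWarnings(as.integer(sub("trial=", "",
                                             w[grepl("^trial=", w)][1])))
    cond <- sub("cond=", "", w[grepl("^cond=", w)][1])
    rows[[length(rows) + 1]] <- data.frame(
      sample = as.integer(round(onset * fs)), type = type,
      trial = if (length(trial) && !is.na(trial)) trial else NA_integer_,
      condition = if (length(cond) && !is.na(cond) && cond != "NA") cond
      else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_events())
  ev <- do.call(rbind, rows)
  ev[order(ev$sample), ]
}
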