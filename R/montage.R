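#' The 24-electrode 10-20 montage used throughout the package
#'
#' Ordered labels of the 24 passive electrodes: ten over the left hemisphere,
#' ten over the right, four along the midline. The reference (FCz) and ground
#' (Fpz) are carried as recording metadata, not as data channels.
#'
#' @return Character vector of 24 channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "F7", "FC1", "C3", "T7", "CP1", "CP5", "TP9", "P3", "O1",
    "Fp2", "F8", "FC2", "C4", "T8", "CP2", "CP6", "TP10", "P4", "O2",
    "Fz", "Cz", "CPz", "Pz")
}

#' Channel groups L1-L6
#'
#' The six anatomical channel groups aggregated alongside the 24 electrodes:
#' L1 left frontal (Fp1, F7, FC1), L2 right frontal (Fp2, F8, FC2),
#' L3 left rear (TP9, CP5, CP1, P3, O1), L4 right rear (TP10, CP6, CP2, P4,
#' O2), L5 = L1 u L3 and L6 = L2 u L4. Together with the electrodes they
#' form the 30 analysis locations.
#'
#' @param montage Channel labels the groups must be contained in.
#' @return Named list of character vectors.
#' @export
channel_groups <- function(montage = default_montage()) {
  g <- list(
    L1 = c("Fp1", "F7", "FC1"),
    L2 = c("Fp2", "F8", "FC2"),
    L3 = c("TP9", "CP5", "CP1", "P3", "O1"),
    L4 = c("TP10", "CP6", "CP2", "P4", "O2")
  )
  g$L5 <- c(g$L1, g$L3)
  g$L6 <- c(g$L2, g$L4)
  missing <- setdiff(unique(unlist(g)), montage)
  if (length(missing))
    stop("channel groups reference channels absent from the montage: ",
         paste(missing, collapse = ", "))
  g
}

#' Analysis locations (electrodes plus channel groups)
#'
#' @inheritParams channel_groups
#' @param groups Named list of channel groups.
#' @return Character vector of location names (montage order, then groups).
#' @export
analysis_locations <- function(montage = default_montage(),
                               groups = channel_groups(montage)) {
  c(montage, names(groups))
}

# channels x samples matrix -> locations x samples matrix (24 electrodes in
# montage order followed by the unweighted group means). Used by the feature
# modules so that a group feature is always computed on the group-averaged
# waveform, never as an average of per-channel features.
location_signals <- function(data, channels, groups) {
  stopifnot(nrow(data) == length(channels))
  out <- data
  rownames(out) <- channels
  if (!length(groups)) return(out)
  gm <- t(vapply(groups, function(ch) group_signal(data, channels, ch),
                 numeric(ncol(data))))
  rownames(gm) <- names(groups)
  rbind(out, gm)
}
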