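#' Score Hidden Figures Test responses
#'
#' Score = number of correct responses minus number of incorrect responses;
#' blanks contribute zero.
#'
#' @param responses Character matrix participants x items with entries
#'   `"correct"`, `"incorrect"`, `"blank"`.
#' @return Integer vector of scores, named by participant.
#' @export
score_hft <- function(responses) {
  bad <- setdiff(unique(as.vector(responses)), c("correct", "incorrect", "blank"))
  if (length(bad)) stop("invalid response values: ", paste(bad, collapse = ", "))
  rowSums(responses == "correct") - rowSums(responses == "incorrect")
}

#' Classify participants as Field Dependent / Neutral / Independent
#'
#' With explicit cutoffs: `score <= low` is FD, `score >= high` is FI,
#' anything strictly between is FN. With `cutoffs = "tertile"` the cutoffs
#' are the empirical 33.3% and 66.7% percentiles and ties at a cutoff are
#' assigned to the lower class (FD at the low cutoff, FN at the high one).
#' The instrument's manual cutoffs are a study input, not derivable from
#' the scores; tertile is the documented default.
#'
#' @param scores Numeric vector of HFT scores.
#' @param cutoffs `"tertile"` or a list/vector with elements `low`, `high`.
#' @return Character vector of classes (`"FD"`, `"FN"`, `"FI"`).
#' @export
classify_fdi <- function(scores, cutoffs = "tertile") {
  if (!length(scores)) stop("scores must be non-empty")
  if (identical(cutoffs, "tertile")) {
    q <- stats::quantile(scores, c(1 / 3, 2 / 3), names = FALSE, type = 7)
    ifelse(scores <= q[1], "FD", ifelse(scores <= q[2], "FN", "FI"))
  } else {
    low <- cutoffs[["low"]]; high <- cutoffs[["high"]]
    if (low >= high) stop("cutoffs: low must be < high")
    ifelse(scores <= low, "FD", ifelse(scores >= high, "FI", "FN"))
  }
}

#' Cronbach's alpha of an item-response matrix
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of totals)` on
#' 0/1 item scores (correct = 1; incorrect and blank = 0).
#'
#' @param responses Character matrix as in [score_hft()], or a numeric 0/1
#'   matrix.
#' @return Numeric scalar.
#' @export
cronbach_alpha <- function(responses) {
  x <- if (is.character(responses)) (responses == "correct") * 1 else responses
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 participants and 2 items")
  totals <- rowSums(x)
  vt <- stats::var(totals)
  if (vt == 0) stop("zero total-score variance; alpha undefined")
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / vt)
}

#' Score and classify a cohort's HFT responses
#'
#' @param responses Character matrix participants x items.
#' @param cutoffs Passed to [classify_fdi()].
#' @return Data frame (participant, score, class) plus the cohort's
#'   Cronbach's alpha as attribute `"alpha"`.
#' @export
hft_results <- function(responses, cutoffs = "tertile") {
  scores <- score_hft(responses)
  out <- data.frame(participant = rownames(responses) %||%
                      sprintf("P%02d", seq_along(scores)),
                    score = as.integer(scores),
                    class = classify_fdi(scores, cutoffs),
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- cronbach_alpha(responses)
  out
}
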