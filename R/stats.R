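#' Paired-sample t-test
#'
#' Two-sided paired t-test on complete pairs: `t = mean(d) / (sd(d)/sqrt(n))`,
#' `df = n - 1`.
#'
#' @param x,y Paired numeric vectors (incomplete pairs are dropped).
#' @return List: `t`, `df`, `p`, `mean_x`, `mean_y`, `n`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs")
  if (stats::sd(x - y) == 0)
    stop("zero difference variance; paired t statistic undefined")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_x = mean(x), mean_y = mean(y), n = n)
}

#' Two-sample (pooled-variance) t-test
#'
#' Student's pooled-variance two-sample t-test, `df = n_a + n_b - 2`
#' (the design's group comparisons use the pooled test: 14 vs 7
#' participants give df = 19).
#'
#' @param a,b Numeric vectors (missing entries dropped).
#' @return List: `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
two_sample_ttest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 observations per group")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("zero pooled variance; t statistic undefined")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = mean(a), mean_b = mean(b), n_a = length(a), n_b = length(b))
}

#' Holm-Bonferroni step-down correction
#'
#' Adjusted p-values `p_(i) = max_{j<=i} min(1, (m-j+1) p_(j))` (ascending
#' order); rejecting adjusted p <= alpha reproduces the classical step-down
#' rule (compare `p_(i)` to `alpha/(m-i+1)`, stop at the first failure).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha Familywise error level.
#' @return List: `p_adjusted` (same order as input), `reject` (logical).
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "holm")
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Run the full comparison matrix
#'
#' The three comparison families of the design: (a) bistable vs unambiguous
#' condition — paired t-tests across participants on the stimulus-onset
#' features 1-9; (b) first vs second button press (bistable condition) —
#' paired t-tests on features 10-12; (c) Field Dependent vs Field
#' Independent — pooled two-sample t-tests on the bistable-condition values
#' of all 12 features (c1 context for features 1-9, second-button context
#' for 10-12). Each test is run at every analysis location;
#' Holm-Bonferroni is applied within the configured family scope (default:
#' per feature, across its 30 locations). Raw and adjusted p-values are
#' both reported.
#'
#' @param features Feature table as produced by the feature modules (long
#'   data frame with participant, group, feature, epoch, location, value).
#' @param alpha Familywise error level.
#' @param family_scope `"feature"` (Holm across locations within each
#'   feature and family), `"global"` (across everything in a family) or
#'   `"none"`.
#' @param families Subset of `c("condition", "button", "group")` to run.
#' @return Data frame of class `eeg_comparisons`: one row per (family,
#'   feature, location) with t, df, p, means, n, p_holm and reject flag.
#' @export
run_comparisons <- function(features, alpha = 0.05,
                            family_scope = c("feature", "global", "none"),
                            families = c("condition", "button", "group")) {
  family_scope <- match.arg(family_scope)
  plans <- list(
    condition = list(features = 1:9, a = "c1", b = "c2", type = "paired"),
    button = list(features = 10:12, a = "b1", b = "b2", type = "paired"),
    group = list(features = 1:12, type = "two_sample"))
  sp <- feature_specs()
  rows <- list()
  for (fam in families) {
    plan <- plans[[fam]]
    fam_rows <- list()
    for (fid in plan$features) {
      if (fam == "group") {
        ctx <- if (fid <= 9) "c1" else "b2"
        sub <- features[features$feature == fid & features$epoch == ctx, ]
        locs <- unique(sub$location)
        for (loc in locs) {
          sl <- sub[sub$location == loc, ]
          a <- sl$value[sl$group == "FD"]
          b <- sl$value[sl$group == "FI"]
          if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) next
          if (stats::var(a, na.rm = TRUE) == 0 &&
              stats::var(b, na.rm = TRUE) == 0) next
          r <- two_sample_ttest(a, b)
          fam_rows[[length(fam_rows) + 1]] <- data.frame(
            family = fam, feature = fid, name = sp$name[fid], location = loc,
            t = r$t, df = r$df, p = r$p, mean_a = r$mean_a, mean_b = r$mean_b,
            n_a = r$n_a, n_b = r$n_b, stringsAsFactors = FALSE)
        }
      } else {
        sub <- features[features$feature == fid &
                          features$epoch %in% c(plan$a, plan$b), ]
        locs <- unique(sub$location)
        for (loc in locs) {
          sl <- sub[sub$location == loc, ]
          wa <- sl[sl$epoch == plan$a, c("participant", "value")]
          wb <- sl[sl$epoch == plan$b, c("participant", "value")]
          m <- merge(wa, wb, by = "participant")
          ok <- stats::complete.cases(m$value.x, m$value.y)
          if (sum(ok) < 2 || stats::sd(m$value.x[ok] - m$value.y[ok]) == 0) next
          r <- paired_ttest(m$value.x, m$value.y)
          fam_rows[[length(fam_rows) + 1]] <- data.frame(
            family = fam, feature = fid, name = sp$name[fid], location = loc,
            t = r$t, df = r$df, p = r$p, mean_a = r$mean_x, mean_b = r$mean_y,
            n_a = r$n, n_b = r$n, stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(fam_rows))
      stop("comparison family '", fam, "' has no runnable tests ",
           "(insufficient participants or missing feature values)")
    fr <- do.call(rbind, fam_rows)
    fr$p_holm <- NA_real_; fr$reject <- NA
    scope_groups <- switch(family_scope,
                           feature = split(seq_len(nrow(fr)), fr$feature),
                           global = list(seq_len(nrow(fr))),
                           none = NULL)
    if (is.null(scope_groups)) {
      fr$p_holm <- fr$p
      fr$reject <- fr$p <= alpha
    } else {
      for (idx in scope_groups) {
        hb <- holm_bonferroni(fr$p[idx], alpha)
        fr$p_holm[idx] <- hb$p_adjusted
        fr$reject[idx] <- hb$reject
      }
    }
    rows[[fam]] <- fr
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "family_scope") <- family_scope
  class(out) <- c("eeg_comparisons", "data.frame")
  out
}

#' Format comparison results as a per-feature report
#'
#' Lists, per family and feature, the locations whose difference passes the
#' threshold, in the style
#' `Fp1 [t(28) = 2.544, p = 0.017, m_a = 3.00, m_b = 2.35]`, with both the
#' raw and the Holm-adjusted p-value.
#'
#' @param comparisons An `eeg_comparisons` object.
#' @param use `"holm"` (adjusted) or `"raw"` to select which p-values
#'   gate the listing.
#' @return Character vector of report lines (invisibly printed).
#' @export
report_comparisons <- function(comparisons, use = c("holm", "raw")) {
  use <- match.arg(use)
  alpha <- attr(comparisons, "alpha") %||% 0.05
  labs <- c(condition = "bistable (c1) vs unambiguous (c2)",
            button = "first vs second button press (c1)",
            group = "Field Dependent vs Field Independent (c1)")
  mlab <- c(condition = c("m_c1", "m_c2"), button = c("m_b1", "m_b2"),
            group = c("m_FD", "m_FI"))
  lines <- character(0)
  for (fam in unique(comparisons$family)) {
    lines <- c(lines, sprintf("== %s ==", labs[[fam]]))
    fsub <- comparisons[comparisons$family == fam, ]
    for (fid in unique(fsub$feature)) {
      sub <- fsub[fsub$feature == fid, ]
      pass <- if (use == "holm") sub$reject else sub$p <= alpha
      hdr <- sprintf("%s (feature %d):", sub$name[1], fid)
      if (!any(pass)) {
        lines <- c(lines, paste(hdr, "no location passes the threshold"))
      } else {
        ml <- mlab[paste0(fam, 1:2)]
        ent <- sprintf("%s [t(%d) = %.3f, p = %.3f, p_holm = %.3f, %s = %.2f, %s = %.2f]",
                       sub$location[pass], sub$df[pass], sub$t[pass],
                       sub$p[pass], sub$p_holm[pass],
                       ml[1], sub$mean_a[pass], ml[2], sub$mean_b[pass])
        lines <- c(lines, hdr, paste0("  ", ent))
      }
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.eeg_comparisons <- function(x, ...) {
  cat(sprintf("<eeg_comparisons> %d tests, alpha = %g, Holm scope '%s'; %d rejections\n",
              nrow(x), attr(x, "alpha"), attr(x, "family_scope"),
              sum(x$reject, na.rm = TRUE)))
  NextMethod()
}
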