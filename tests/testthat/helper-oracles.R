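# Independent brute-force / closed-form oracles used by the tests. These
# deliberately re-derive every quantity from first principles and share no
# code with the implementation they check.

# Exhaustive local-peak scan: tests every sample's neighbourhood directly.
peak_oracle <- function(x, fs, window_ms, polarity, t_start_ms = 0,
                        neighborhood_ms = 20) {
  i0 <- round((window_ms[1] - t_start_ms) * fs / 1000) + 1
  i1 <- round((window_ms[2] - t_start_ms) * fs / 1000) + 1
  idx <- i0:i1
  wf <- if (polarity == "positive") x else -x
  w <- wf[idx]
  nb <- round(neighborhood_ms * fs / 1000)
  local <- logical(length(idx))
  for (j in seq_along(idx)) {
    p <- idx[j]
    ok <- TRUE
    for (q in max(1, p - nb):min(length(wf), p + nb)) {
      if (q != p && wf[q] >= wf[p]) { ok <- FALSE; break }
    }
    local[j] <- ok
  }
  cand <- if (any(local)) which(local) else seq_along(idx)
  best <- cand[order(-w[cand], cand)][1]
  list(amplitude_uv = x[idx[best]],
       latency_ms = t_start_ms + (idx[best] - 1) * 1000 / fs,
       is_local = any(local))
}

# Textbook paired t-test: statistic from the definition, p by t CDF.
paired_oracle <- function(x, y) {
  d <- x - y
  n <- length(d)
  tstat <- mean(d) / (sqrt(sum((d - mean(d))^2) / (n - 1)) / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * stats::pt(-abs(tstat), n - 1))
}

# Textbook pooled-variance two-sample t-test.
two_sample_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, df = na + nb - 2, p = 2 * stats::pt(-abs(tstat), na + nb - 2))
}

# Hand-executable Holm step-down: walk the sorted p-values, compare each to
# alpha / (m - i + 1), stop at the first failure.
holm_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) reject[o[i]] <- TRUE else break
  }
  adj_sorted <- cummax(pmin(1, (m - seq_len(m) + 1) * p[o]))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  list(reject = reject, p_adjusted = adj)
}

# Direct one-sided periodogram of a Hamming-windowed, mean-removed segment
# (independent of welch_psd's internals).
periodogram_oracle <- function(x, fs, nfft = length(x)) {
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, length(x) - 1) / (length(x) - 1))
  xd <- (x - mean(x)) * w
  X <- fft(c(xd, numeric(nfft - length(x))))
  P <- Mod(X[1:(nfft %/% 2 + 1)])^2 / (fs * sum(w^2))
  sc <- rep(2, length(P)); sc[1] <- 1
  if (nfft %% 2 == 0) sc[length(P)] <- 1
  P * sc
}
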