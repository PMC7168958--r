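# Brute-force reference implementations, independent of the package's
# computational paths, used to pin down numerical behaviour.

# SampEn by explicit O(W^2) double loop over template pairs
sampen_oracle <- function(x, m = 2, r = 0.2 * sqrt(mean((x - mean(x))^2))) {
  n <- length(x)
  A <- 0; B <- 0
  for (i in seq_len(n - m - 1)) {
    for (j in (i + 1):(n - m)) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  cap <- log((n - m) * (n - m - 1))
  if (B == 0 || A == 0) return(cap)
  min(-log(A / B), cap)
}

# normalized cross-correlation peak/lag by explicit lag scan
xcorr_oracle <- function(x, y, rate) {
  W <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den <= 0) return(c(peak = 0, lag = 0))
  lags <- -(W - 1):(W - 1)
  z <- vapply(lags, function(d) {
    i <- max(1, 1 + d):min(W, W + d)  # y index i - d stays in 1..W
    sum(xc[i] * yc[i - d]) / den
  }, numeric(1))
  best <- max(z)
  cand <- which(z >= best - 1e-12)
  pick <- cand[order(abs(lags[cand]), lags[cand])][1]
  c(peak = z[pick], lag = lags[pick] / rate)
}

# AUROC by explicit pairwise concordance counting, ties worth 1/2
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Holm step-down adjusted p-values, written out longhand
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj_sorted[i] <- min(run, 1)
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}
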