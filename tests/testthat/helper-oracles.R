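# Independent brute-force oracles used across the suite.

# naive sort-based centered running median with reflected edges
naive_running_median <- function(x, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  if (k <= 1L) return(x)
  h <- (k - 1L) %/% 2L
  n <- length(x)
  xp <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  vapply(seq_len(n), function(i) {
    w <- sort(xp[i:(i + k - 1L)])
    w[h + 1L]
  }, numeric(1))
}

# brute-force sample entropy via embedding + stats::dist (Chebyshev metric);
# independent of the package's C counting loop
sampen_oracle <- function(y, m, r_abs) {
  n <- length(y)
  nt <- n - m
  emb <- function(d) {
    t(vapply(seq_len(nt), function(i) y[i:(i + d - 1L)], numeric(d)))
  }
  count_pairs <- function(d) {
    D <- as.matrix(stats::dist(emb(d), method = "maximum"))
    sum(D[upper.tri(D)] <= r_abs)
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  if (A == 0 || B == 0) return(NaN)
  -log(A / B)
}

# loop-written coarse-graining oracles
coarse_trad_oracle <- function(x, tau) {
  nb <- length(x) %/% tau
  vapply(seq_len(nb), function(j) mean(x[((j - 1) * tau + 1):(j * tau)]),
         numeric(1))
}
coarse_impr_oracle <- function(x, tau) {
  if (tau == 1) return(as.numeric(x))
  step <- max(1, floor(tau / 2 + 0.5))
  starts <- seq(1, length(x) - tau + 1, by = step)
  vapply(starts, function(s) mean(x[s:(s + tau - 1)]), numeric(1))
}

# greedy one-to-one peak matching within a sample tolerance
match_peaks <- function(detected, truth, tol) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (p in truth) {
    j <- which(!used & abs(detected - p) <= tol)
    if (length(j)) {
      used[j[which.min(abs(detected[j] - p))]] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp,
       recall = if (length(truth)) tp / length(truth) else NA_real_,
       precision = if (length(detected)) tp / length(detected) else NA_real_)
}

peak_f1 <- function(detected, truth, tol) {
  m <- match_peaks(detected, truth, tol)
  if (is.na(m$precision) || m$precision + m$recall == 0) return(0)
  2 * m$precision * m$recall / (m$precision + m$recall)
}
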