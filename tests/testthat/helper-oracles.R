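# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops and explicit formulas.

# Simple OLS by normal equations; r2 as 1 - SSE/SST.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = 1 - sse / sst)
}

# Exhaustive O(N*W) scan for the greatest mean over a sliding window.
brute_max_sustained <- function(samples, fs, window, start_time = 0) {
  w <- as.integer(round(window * fs))
  best <- -Inf; best_i <- NA_integer_
  for (i in seq_len(length(samples) - w + 1L)) {
    m <- sum(samples[i:(i + w - 1L)]) / w
    if (m > best) { best <- m; best_i <- i }
  }
  list(value = best, window_start = start_time + (best_i - 1L) / fs)
}

# Brute-force search over all k-subsets minimizing total |value - median|.
brute_rest_subset <- function(values, k = 6) {
  med <- median(values)
  combos <- utils::combn(seq_along(values), k)
  costs <- apply(combos, 2, function(idx) sum(abs(values[idx] - med)))
  best <- which(costs <= min(costs) + 1e-12)
  # among optimal subsets prefer the lexicographically earliest (trial order)
  lex <- sapply(best, function(j) paste(sprintf("%03d", combos[, j]), collapse = ""))
  sort(combos[, best[which.min(lex)]])
}

# Squared magnitude response of an order-n Butterworth low-pass (one pass).
butter_mag2 <- function(f, cutoff, order) 1 / (1 + (f / cutoff)^(2 * order))

# A quiet ground truth for deterministic pipeline tests.
quiet_gt <- function(va = 0.7, m_full = 10, t0 = 0.15 * m_full,
                     arm = "a1", group = "biceps", posture = "horizontal",
                     ...) {
  arm_ground_truth(arm, group, posture, m_full, va, t0, noise_sd = 0, ...)
}

# Protocol with effort jitter disabled so plateaus hit targets exactly.
exact_protocol <- function(...) protocol_spec(hold_tolerance = 0, ...)
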