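# Independent reference implementations used to cross-check the package.

# Brute-force peak detector: exhaustive O(n^2) scan applying the height,
# prominence and separation rules literally.  Only for short series.
oracle_find_peaks <- function(v, min_height, min_prominence, sep_samples,
                              height_gate = TRUE) {
  n <- length(v)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (v[i] > v[i - 1] && v[i] > v[i + 1]) cand <- c(cand, i)
  }
  if (height_gate) cand <- cand[v[cand] >= min_height]

  prom_ok <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    higher_left <- which(v[seq_len(i - 1)] > v[i])
    lo <- if (length(higher_left)) max(higher_left) + 1 else 1
    left_base <- min(v[lo:i])
    higher_right <- which(v[(i + 1):n] > v[i]) + i
    hi <- if (length(higher_right)) min(higher_right) - 1 else n
    right_base <- min(v[i:hi])
    prom_ok[k] <- (v[i] - max(left_base, right_base)) >= min_prominence
  }
  cand <- cand[prom_ok]

  # separation: repeatedly accept the highest remaining (earliest on ties)
  kept <- integer(0)
  remaining <- cand
  while (length(remaining)) {
    best <- remaining[order(-v[remaining], remaining)][1]
    kept <- c(kept, best)
    remaining <- remaining[abs(remaining - best) >= sep_samples - 1e-9 &
                           remaining != best]
  }
  sort(kept)
}

# Semi-analytic per-sample flip probability for threshold crossing under
# additive Gaussian noise: P(flip at t) = Phi(-|V(t) - theta| / sigma).
oracle_flip_rate <- function(values, theta, sigma) {
  p <- pnorm(-abs(values - theta) / sigma)
  list(mean = mean(p), se = sqrt(sum(p * (1 - p))) / length(p))
}

make_sine_ts <- function(A, T, duration, rate = 1, alpha = 0, label = "X") {
  generate_channel(channel_params(label, A, T, alpha), duration, rate)
}
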