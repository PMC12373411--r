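# Independent brute-force oracles used across tests. These deliberately
# re-derive each quantity from first principles, sample by sample, so they
# share no code with the package implementations they check.

# exhaustive peak scan: check every index against the three conditions
oracle_peaks <- function(x, fs, z_threshold = 2, min_separation_s = 0.25) {
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) return(integer(0))
  z <- (x - mu) / sigma
  n <- length(x)
  kept <- integer(0)
  last <- -Inf
  min_gap <- min_separation_s * fs - sqrt(.Machine$double.eps)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    if (z[i] < z_threshold) next
    if (!(z[i - 1] <= z[i] && z[i] >= z[i + 1])) next
    if (i - last < min_gap) next
    kept <- c(kept, i)
    last <- i
  }
  kept
}

# textbook paired t: mean(d) / (sd(d) / sqrt(n)), d = pre - post
oracle_paired_t <- function(pre, post) {
  d <- pre - post
  n <- length(d)
  tt <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * stats::pt(-abs(tt), n - 1))
}

# the mentally-well rule evaluated directly on one 14-vector of codes
oracle_classify <- function(items, threshold = 4) {
  hedonic <- sum(items[1:3] >= threshold)
  eudemonic <- sum(items[4:14] >= threshold)
  if (hedonic >= 1 && eudemonic >= 6) "mentally_well" else "moderate"
}

# acceleration-magnitude-like random series with embedded spikes, so peak
# tests exercise both dense noise and clear events
random_accel_series <- function(n, spike_rate = 0.02) {
  x <- abs(stats::rnorm(n, 10, 1.5))
  k <- stats::rbinom(1, n, spike_rate)
  if (k > 0) {
    at <- sample.int(n, k)
    x[at] <- x[at] + stats::runif(k, 3, 12)
  }
  x
}

mhcsf_response_row <- function(items, participant_id = "P01", week = 1) {
  stopifnot(length(items) == 14)
  out <- tibble::tibble(participant_id = participant_id, week = week)
  out[sprintf("item_%02d", 1:14)] <- as.list(as.numeric(items))
  out
}
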