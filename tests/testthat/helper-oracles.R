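# Independent brute-force reference implementations, written from the
# formulas directly with explicit loops. They never call package internals.

oracle_sd <- function(x, divisor) {
  m <- sum(x) / length(x)
  acc <- 0
  for (xi in x) acc <- acc + (xi - m)^2
  sqrt(acc / divisor)
}

oracle_pivd <- function(track) {
  num_f <- length(track)
  d <- numeric(num_f - 1L)
  for (i in seq_len(num_f - 1L)) d[i] <- track[i + 1L] - track[i]
  oracle_sd(d, num_f - 1L)
}

oracle_delta2 <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  clamp <- function(i) min(max(i, 1L), n)
  for (i in seq_len(n)) for (k in seq_len(ncol(m))) {
    out[i, k] <- (-2 * m[clamp(i - 2L), k] - m[clamp(i - 1L), k] +
                    m[clamp(i + 1L), k] + 2 * m[clamp(i + 2L), k]) / 3
  }
  out
}

oracle_afvc <- function(m, dm) {
  ps <- numeric(24)
  for (k in 1:12) ps[k] <- sum(m[, k]) / nrow(m)
  for (k in 1:12) ps[12 + k] <- sum(dm[, k]) / nrow(dm)
  mean_ps <- sum(ps) / 24
  oracle_sd(ps, 24) / abs(mean_ps)
}

oracle_head_trajectory <- function(arr) {
  n <- dim(arr)[1L]
  hm_r <- numeric(n - 1L); hm_u <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    sx <- 0; sy <- 0
    for (p in 1:17) {
      sx <- sx + arr[i + 1L, p, 1L] - arr[i, p, 1L]
      sy <- sy + arr[i + 1L, p, 2L] - arr[i, p, 2L]
    }
    hm_r[i] <- sx / 17; hm_u[i] <- sy / 17
  }
  list(hm_r = hm_r, hm_u = hm_u)
}

oracle_uhd <- function(hm_u, n_l) {
  acc <- 0
  for (v in hm_u) acc <- acc + abs(v)
  acc / n_l
}

oracle_mar <- function(arr) {
  n <- dim(arr)[1L]
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- sqrt((arr[i, 52, 1] - arr[i, 58, 1])^2 + (arr[i, 52, 2] - arr[i, 58, 2])^2)
    l <- sqrt((arr[i, 49, 1] - arr[i, 55, 1])^2 + (arr[i, 49, 2] - arr[i, 55, 2])^2)
    out[i] <- w / l
  }
  out
}

# random 68-point landmark array helper
random_landmarks <- function(n_frames, seed = 1, scale = 5) {
  set.seed(seed)
  arr <- array(stats::rnorm(n_frames * 68 * 2, 300, scale),
               dim = c(n_frames, 68, 2))
  arr
}
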