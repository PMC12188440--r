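# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops and textbook formulas only.

oracle_running_mean <- function(x, window) {
  n <- length(x)
  h <- floor(window / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1, n - i)
    w <- x[(i - hi):(i + hi)]
    out[i] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  out
}

# linear-interpolation quantile (Hyndman-Fan type 7), written from the
# definition
oracle_quantile7 <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_polarization <- function(angles) {
  sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
}

# leading eigenvector of a symmetric non-negative matrix by power iteration
oracle_power_iteration <- function(W, tol = 1e-12, max_iter = 100000) {
  v <- rep(1, nrow(W))
  for (i in seq_len(max_iter)) {
    v2 <- as.vector(W %*% v)
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < tol) break
    v <- v2
  }
  v2 / max(v2)
}

# per-focal nearest neighbour by direct scan
oracle_nearest <- function(xs, ys, ids, focal) {
  fi <- which(ids == focal)
  best <- Inf
  who <- NA_character_
  for (j in seq_along(ids)) {
    if (j == fi) next
    d <- sqrt((xs[j] - xs[fi])^2 + (ys[j] - ys[fi])^2)
    if (d < best || (d == best && ids[j] < who)) {
      best <- d
      who <- ids[j]
    }
  }
  who
}

# first-order transition probabilities by counting consecutive pairs
oracle_transitions <- function(states) {
  u <- sort(unique(states))
  cnt <- matrix(0, length(u), length(u), dimnames = list(u, u))
  for (i in seq_len(length(states) - 1)) {
    cnt[states[i], states[i + 1]] <- cnt[states[i], states[i + 1]] + 1
  }
  cnt / ifelse(rowSums(cnt) > 0, rowSums(cnt), NA)
}
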