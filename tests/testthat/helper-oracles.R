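# Independent loop-based oracles for the four summary measures and the
# evaluation statistics. These are deliberately naive (scalar loops,
# textbook formulas) and share no code with the package internals.

naive_enmonz <- function(x, y, z) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    out[t] <- max(sqrt(x[t]^2 + y[t]^2 + z[t]^2) - 1, 0)
  }
  out
}

naive_mad <- function(x, y, z, N) {
  n_win <- length(x) %/% N
  out <- numeric(n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * N + 1):(w * N)
    en <- sqrt(x[idx]^2 + y[idx]^2 + z[idx]^2)
    mu <- sum(en) / N
    out[w] <- sum(abs(en - mu)) / N
  }
  out
}

naive_ai <- function(x, y, z, N, noise_var = 0) {
  n_win <- length(x) %/% N
  out <- numeric(n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * N + 1):(w * N)
    s <- 0
    for (a in list(x[idx], y[idx], z[idx])) {
      mu <- sum(a) / N
      s <- s + sum((a - mu)^2) / N
    }
    out[w] <- max(s / 3 - noise_var, 0)
  }
  out
}

# Successive-difference norm followed by a centered running lower-median
# with shrinking windows (window k covers [i-(k-1)%/%2, i+k%/%2]).
naive_rocam <- function(x, y, z, k) {
  n <- length(x)
  d <- numeric(n)
  for (t in 2:n) {
    d[t] <- sqrt((x[t] - x[t - 1])^2 + (y[t] - y[t - 1])^2 +
                   (z[t] - z[t - 1])^2)
  }
  d[1] <- d[2]
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - (k - 1) %/% 2)
    hi <- min(n, i + k %/% 2)
    w <- sort(d[lo:hi])
    out[i] <- w[(length(w) - 1) %/% 2 + 1]  # lower median
  }
  out
}

# Spearman via explicit average ranks then the product-moment formula.
spearman_oracle <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# KS statistic by exhaustive ECDF-difference scan over all jump points.
ks_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  d <- 0
  for (p in pts) {
    d <- max(d, abs(mean(a <= p) - mean(b <= p)))
  }
  d
}
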