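# Internal helpers: classed conditions and small numeric utilities.

stop_wristpa <- function(msg, class) {
  stop(structure(
    class = c(paste0("wristpa_", class), "wristpa_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

warn_wristpa <- function(msg, class = "warning") {
  warning(structure(
    class = c(paste0("wristpa_", class), "wristpa_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FFT-based open convolution; pads to a 2-3-5 smooth length so day-long
# streams (~10^7 samples) stay fast.
fft_convolve <- function(x, h) {
  n_out <- length(x) + length(h) - 1L
  nf <- stats::nextn(n_out, factors = c(2L, 3L, 5L))
  X <- stats::fft(c(x, numeric(nf - length(x))))
  H <- stats::fft(c(h, numeric(nf - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n_out)] / nf
}

# Best rational approximation p/q to `num/den` by continued fractions.
rational_ratio <- function(num, den, max_den = 10000L, tol = 1e-9) {
  x <- num / den
  a0 <- floor(x)
  p0 <- a0; q0 <- 1
  p1 <- 1; q1 <- 0
  r <- x - a0
  while (abs(p0 / q0 - x) > tol * x) {
    if (r < .Machine$double.eps || q0 > max_den) break
    r <- 1 / r
    a <- floor(r)
    r <- r - a
    pn <- a * p0 + p1
    qn <- a * q0 + q1
    p1 <- p0; q1 <- q0
    p0 <- pn; q0 <- qn
  }
  if (q0 > max_den || abs(p0 / q0 - x) > tol * max(x, 1)) {
    return(NULL)
  }
  list(p = as.integer(p0), q = as.integer(q0))
}

# Group means of `x` by a dense integer index 1..n_groups (fast path used by
# epoch and window aggregation).
group_means <- function(x, index, n_groups) {
  sums <- unname(rowsum(x, index, reorder = TRUE))
  cnts <- tabulate(index, nbins = n_groups)
  present <- sort(unique(index))
  out <- rep(NA_real_, n_groups)
  out[present] <- sums[, 1] / cnts[present]
  out
}
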