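#' @title Anti-aliased down-sampling of tri-axial streams
#' @name resampling
#' @description Rational-ratio down-sampling with a linear-phase FIR
#'   anti-aliasing filter (Kaiser window design, stopband >= 60 dB, passband
#'   edge at 0.45 x target rate). Filtering is zero-phase compensated
#'   (symmetric filter, integer group delay removed) with reflect padding,
#'   and each polyphase branch is normalized to unit DC gain so constant
#'   signals pass through exactly.
NULL

design_antialias_fir <- function(target_rate_hz, intermediate_rate_hz,
                                 stopband_db = 60, cutoff_factor = 0.45) {
  f_pass <- cutoff_factor * target_rate_hz
  f_stop <- 0.55 * target_rate_hz
  dev <- 10^(-stopband_db / 20)
  ko <- signal::kaiserord(c(f_pass, f_stop), c(1, 0), c(dev, dev),
                          intermediate_rate_hz)
  n <- ko$n
  if (n %% 2L == 1L) n <- n + 1L  # even order -> odd length, integer delay
  h <- signal::fir1(n, ko$Wc[1], type = "low",
                    window = signal::kaiser(n + 1, ko$beta), scale = FALSE)
  as.numeric(h)
}

#' Down-sample a tri-axial record
#'
#' Each axis is low-pass filtered at the target Nyquist band and decimated;
#' non-integer ratios are handled by rational (zero-stuffing) resampling.
#' Output timestamps are regenerated on the target grid. The first and last
#' 60 s of the output are flagged as an edge region which
#' [epoch_aggregate()] marks unknown by default (`trim_edges = FALSE`
#' disables the flag).
#'
#' @param record A [triaxial_record()].
#' @param target_rate_hz Target sample rate (<= the record's rate).
#' @param stopband_db Minimum stopband attenuation of the FIR design.
#' @param trim_edges Flag the first/last 60 s for exclusion from epoch
#'   statistics (default `TRUE`).
#' @return A [triaxial_record()] at the target rate, of length
#'   `floor(n * target/source)`.
#' @export
downsample <- function(record, target_rate_hz, stopband_db = 60,
                       trim_edges = TRUE) {
  fs <- record$sample_rate_hz
  if (target_rate_hz > fs) {
    stop_wristpa("up-sampling is not supported (information above the source Nyquist cannot be recovered)",
                 "unsupported_error")
  }
  if (target_rate_hz == fs) return(record)
  rat <- rational_ratio(target_rate_hz, fs)
  if (is.null(rat)) {
    stop_wristpa("target/source rate ratio is not a manageable rational number",
                 "config_error")
  }
  p <- rat$p; q <- rat$q
  h <- design_antialias_fir(target_rate_hz, fs * p, stopband_db)
  # unit DC gain per polyphase branch -> constants preserved exactly
  L <- length(h)
  for (ph in seq_len(p)) {
    idx <- seq(ph, L, by = p)
    h[idx] <- h[idx] / sum(h[idx])
  }
  d <- (L - 1L) %/% 2L            # integer group delay of the odd-length FIR
  n <- length(record$x)
  pad <- min(n - 1L, ceiling(d / p) + 1L)
  m <- floor(n * p / q)
  one_axis <- function(a) {
    apad <- c(a[(pad + 1L):2L], a, a[(n - 1L):(n - pad)])
    if (p > 1L) {
      up <- numeric(length(apad) * p)
      up[seq(1L, by = p, length.out = length(apad))] <- apad
    } else {
      up <- apad
    }
    y <- fft_convolve(up, h)
    # zero-phase sample aligned with unpadded sample grid
    y[(pad * p) + (seq_len(m) - 1L) * q + 1L + d]
  }
  t0 <- record$time[1]
  out <- triaxial_record(
    time = t0 + (seq_len(m) - 1L) / target_rate_hz,
    x = one_axis(record$x), y = one_axis(record$y), z = one_axis(record$z),
    sample_rate_hz = target_rate_hz,
    dynamic_range_g = record$dynamic_range_g
  )
  if (trim_edges) attr(out, "edge_seconds") <- 60
  out
}

#' Down-sample to several rates independently
#'
#' Each rate is processed from the original record (not cascaded).
#'
#' @param record A [triaxial_record()].
#' @param rates Numeric vector of target rates, each <= the record's rate.
#' @param ... Passed to [downsample()].
#' @return Named list (one [triaxial_record()] per rate).
#' @export
resample_all <- function(record, rates, ...) {
  setNames(lapply(rates, function(r) downsample(record, r, ...)),
           paste0(rates, "hz"))
}
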