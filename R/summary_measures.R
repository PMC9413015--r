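#' @title Acceleration summary measures
#' @name summary_measures
#' @description The four scalar summaries of tri-axial acceleration used
#'   throughout the package, all in gravitational units (g):
#'   \describe{
#'     \item{ENMONZ}{Euclidean norm minus one, clamped at zero:
#'       `max(sqrt(x^2+y^2+z^2) - 1, 0)` per sample.}
#'     \item{MAD}{mean amplitude deviation: within a window of N samples,
#'       the mean absolute deviation of the Euclidean norm from its window
#'       mean.}
#'     \item{AI}{Activity Index: per 1-second window, the mean of the three
#'       per-axis population variances, minus an optional device noise
#'       variance, clamped at zero; 1-second values are summed per minute.}
#'     \item{ROCAM}{rate-of-change acceleration movement: the Euclidean norm
#'       of the successive per-axis differences, passed through a running
#'       median whose length equals the number of samples in one second.}
#'   }
#'   All measures are summarized on 1-minute epochs (mean of intermediate
#'   values; AI uses the sum of its sixty 1-second values).
NULL

#' Configuration for the summary measures
#'
#' @param mad_window_seconds Window length for MAD in seconds (default 60,
#'   i.e. the full epoch, so the epoch average is over a single window).
#' @param ai_noise_variance Device noise variance subtracted inside AI
#'   (default 0; in g^2).
#' @param epoch_seconds Epoch length (fixed at 60).
#' @return A `measure_config` list. The AI window (1 s) and the ROCAM
#'   median-filter length (1 s of samples) are fixed by definition.
#' @export
measure_config <- function(mad_window_seconds = 60, ai_noise_variance = 0,
                           epoch_seconds = 60) {
  if (mad_window_seconds <= 0 || ai_noise_variance < 0) {
    stop_wristpa("windows must be positive and noise variance >= 0",
                 "config_error")
  }
  structure(list(mad_window_seconds = mad_window_seconds,
                 ai_window_seconds = 1,
                 ai_noise_variance = ai_noise_variance,
                 rocam_median_window_seconds = 1,
                 epoch_seconds = epoch_seconds),
            class = "measure_config")
}

# Internal container for intermediate (pre-epoch) measure values:
# one value per window of `step_seconds`, stamped by window start time.
measure_series <- function(time, values, measure, step_seconds,
                           sample_rate_hz, edge_seconds = 0) {
  structure(list(time = time, values = values, measure = measure,
                 step_seconds = step_seconds,
                 sample_rate_hz = sample_rate_hz,
                 edge_seconds = edge_seconds),
            class = "measure_series")
}

en_norm <- function(record) {
  sqrt(record$x^2 + record$y^2 + record$z^2)
}

#' Per-sample ENMONZ series
#'
#' @param record A [triaxial_record()].
#' @return A per-sample `measure_series` (g).
#' @export
enmonz <- function(record) {
  v <- pmax(en_norm(record) - 1, 0)
  measure_series(record$time, v, "enmonz", 1 / record$sample_rate_hz,
                 record$sample_rate_hz,
                 attr(record, "edge_seconds") %||% 0)
}

#' Per-window MAD series
#'
#' @param record A [triaxial_record()].
#' @param config A [measure_config()].
#' @return A `measure_series` with one value per `mad_window_seconds`
#'   window (g). Trailing partial windows are dropped.
#' @export
mad_measure <- function(record, config = measure_config()) {
  fs <- record$sample_rate_hz
  N <- round(config$mad_window_seconds * fs)
  n <- length(record$time)
  if (N < 2L) stop_wristpa("MAD window must contain >= 2 samples", "config_error")
  if (N > n) stop_wristpa("MAD window longer than the record", "data_error")
  en <- en_norm(record)
  n_win <- n %/% N
  en <- en[seq_len(n_win * N)]
  m <- matrix(en, nrow = N)
  mu <- colMeans(m)
  v <- colMeans(abs(m - rep(mu, each = N)))
  t0 <- record$time[seq(1, by = N, length.out = n_win)]
  measure_series(t0, v, "mad", config$mad_window_seconds, fs,
                 attr(record, "edge_seconds") %||% 0)
}

#' Per-second Activity Index series
#'
#' @param record A [triaxial_record()].
#' @param config A [measure_config()].
#' @return A `measure_series` with one value per second. Per-axis variances
#'   use the population (1/N) form; the mean across axes is reduced by
#'   `ai_noise_variance` and clamped at zero.
#' @export
activity_index <- function(record, config = measure_config()) {
  fs <- record$sample_rate_hz
  N <- round(config$ai_window_seconds * fs)
  if (N < 2L) {
    stop_wristpa("AI needs >= 2 samples per 1-second window", "data_error")
  }
  n <- length(record$time)
  n_win <- n %/% N
  idx <- seq_len(n_win * N)
  pop_var_cols <- function(a) {
    m <- matrix(a[idx], nrow = N)
    colMeans(m^2) - colMeans(m)^2
  }
  v3 <- (pop_var_cols(record$x) + pop_var_cols(record$y) +
           pop_var_cols(record$z)) / 3
  v <- pmax(v3 - config$ai_noise_variance, 0)
  t0 <- record$time[seq(1, by = N, length.out = n_win)]
  measure_series(t0, v, "ai", config$ai_window_seconds, fs,
                 attr(record, "edge_seconds") %||% 0)
}

#' Per-sample ROCAM series
#'
#' Euclidean norm of successive per-axis differences, median-filtered over a
#' 1-second window. The undefined first difference is set equal to the
#' second before filtering so output length equals record length. The median
#' filter uses shrinking windows at the edges and the lower median for even
#' window lengths.
#'
#' @param record A [triaxial_record()].
#' @param config A [measure_config()].
#' @return A per-sample `measure_series` (g).
#' @export
rocam <- function(record, config = measure_config()) {
  n <- length(record$time)
  if (n < 2L) stop_wristpa("ROCAM needs a record of length >= 2", "data_error")
  d <- sqrt(diff(record$x)^2 + diff(record$y)^2 + diff(record$z)^2)
  d <- c(d[1], d)
  k <- max(1L, as.integer(round(config$rocam_median_window_seconds *
                                  record$sample_rate_hz)))
  v <- rolling_median_lower(d, k)
  measure_series(record$time, v, "rocam", 1 / record$sample_rate_hz,
                 record$sample_rate_hz,
                 attr(record, "edge_seconds") %||% 0)
}

#' Aggregate intermediate measure values into 1-minute epochs
#'
#' Epochs are clock-aligned to the minute grid; the epoch labeled `t` covers
#' `[t, t + 60)` seconds. ENMONZ, MAD, and ROCAM epochs are the mean of the
#' intermediate values; AI epochs are the sum of the sixty 1-second values.
#' Epochs with incomplete raw coverage - including any epoch overlapping a
#' resampling edge transient (see [downsample()]) - are marked unknown
#' (`NA`). Partial leading/trailing minutes are dropped.
#'
#' @param ms A `measure_series` from [enmonz()], [mad_measure()],
#'   [activity_index()], or [rocam()].
#' @param epoch_seconds Epoch length (default 60).
#' @return An [epoch_series()].
#' @export
epoch_aggregate <- function(ms, epoch_seconds = 60) {
  stopifnot(inherits(ms, "measure_series"))
  per_epoch <- epoch_seconds / ms$step_seconds
  if (abs(per_epoch - round(per_epoch)) > 1e-8) {
    stop_wristpa("epoch length is not a multiple of the measure window",
                 "config_error")
  }
  per_epoch <- round(per_epoch)
  t0 <- ceiling(ms$time[1] / epoch_seconds) * epoch_seconds
  t_end <- ms$time[length(ms$time)] + ms$step_seconds
  n_ep <- floor((t_end - t0) / epoch_seconds + 1e-9)
  if (n_ep < 1L) {
    stop_wristpa("series does not cover a full epoch", "data_error")
  }
  keep <- ms$time >= t0 - 1e-9 & ms$time < t0 + n_ep * epoch_seconds - 1e-9
  tm <- ms$time[keep]
  vv <- ms$values[keep]
  idx <- as.integer(floor((tm - t0) / epoch_seconds + 1e-9)) + 1L
  means <- group_means(vv, idx, n_ep)
  cnts <- tabulate(idx, nbins = n_ep)
  vals <- if (ms$measure == "ai") means * cnts else means
  vals[cnts < per_epoch] <- NA_real_
  if (ms$edge_seconds > 0) {
    starts <- t0 + (seq_len(n_ep) - 1) * epoch_seconds
    lo <- ms$time[1] + ms$edge_seconds
    hi <- t_end - ms$edge_seconds
    vals[starts < lo - 1e-9 | (starts + epoch_seconds) > hi + 1e-9] <- NA_real_
  }
  epoch_series(t0 + (seq_len(n_ep) - 1) * epoch_seconds, vals, ms$measure,
               ms$sample_rate_hz)
}

#' Compute epoch series for several measures at once
#'
#' @param record A [triaxial_record()].
#' @param measures Character vector among `enmonz`, `mad`, `ai`, `rocam`.
#' @param config A [measure_config()].
#' @return Named list of [epoch_series()].
#' @export
summarize_record <- function(record,
                             measures = c("enmonz", "mad", "ai", "rocam"),
                             config = measure_config()) {
  measures <- match.arg(tolower(measures),
                        c("enmonz", "mad", "ai", "rocam"), several.ok = TRUE)
  fn <- list(enmonz = function(r) enmonz(r),
             mad = function(r) mad_measure(r, config),
             ai = function(r) activity_index(r, config),
             rocam = function(r) rocam(r, config))
  setNames(lapply(measures, function(m) epoch_aggregate(fn[[m]](record),
                                                        config$epoch_seconds)),
           measures)
}
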