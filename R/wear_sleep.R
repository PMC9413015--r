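#' @title Non-wear and sleep segmentation
#' @name wear_sleep
#' @description Minute-grid segmentation applied before activity
#'   classification: non-wear is detected as prolonged stationarity (runs of
#'   >= 60 stationary minutes by default), and sleep in two stages -
#'   candidate minutes with low ROCAM and a high fraction of quiet 1-second
#'   sub-windows, then joining of candidate segments across short gaps and
#'   retention of sufficiently long joined blocks.
NULL

#' Non-wear detection parameters
#'
#' @param min_duration_minutes Minimum stationary run flagged as non-wear
#'   (default 60 min).
#' @param stationarity_sd_g Per-axis within-minute standard-deviation
#'   ceiling for a minute to count as stationary (default 0.013 g, a widely
#'   used stationarity convention).
#' @return A `nonwear_params` list.
#' @export
nonwear_params <- function(min_duration_minutes = 60,
                           stationarity_sd_g = 0.013) {
  if (min_duration_minutes < 1 || stationarity_sd_g <= 0) {
    stop_wristpa("min_duration_minutes >= 1 and stationarity_sd_g > 0 required",
                 "config_error")
  }
  structure(list(min_duration_minutes = min_duration_minutes,
                 stationarity_sd_g = stationarity_sd_g),
            class = "nonwear_params")
}

#' Sleep detection parameters
#'
#' @param candidate_threshold ROCAM level (g) below which a minute can be a
#'   sleep candidate. The default, 0.06 g, is the sedentary floor of the
#'   default ROCAM threshold set (sleep sits below the lowest sedentary
#'   threshold).
#' @param quiet_fraction Minimum fraction of a candidate minute's 1-second
#'   sub-windows whose mean ROCAM is below the threshold (default 0.9).
#' @param join_gap_minutes Maximum gap bridged when joining candidate
#'   segments (default 30).
#' @param min_block_minutes Minimum joined-block duration accepted as sleep
#'   (default 30).
#' @return A `sleep_params` list.
#' @export
sleep_params <- function(candidate_threshold = 0.06, quiet_fraction = 0.9,
                         join_gap_minutes = 30, min_block_minutes = 30) {
  if (candidate_threshold <= 0 || quiet_fraction <= 0 || quiet_fraction > 1 ||
      join_gap_minutes <= 0 || min_block_minutes <= 0) {
    stop_wristpa("sleep parameters must be positive with quiet_fraction in (0, 1]",
                 "config_error")
  }
  structure(list(candidate_threshold = candidate_threshold,
                 quiet_fraction = quiet_fraction,
                 join_gap_minutes = join_gap_minutes,
                 min_block_minutes = min_block_minutes),
            class = "sleep_params")
}

# Minute grid of a record: start times of complete minutes, plus the sample
# index of each minute for grouped statistics.
minute_grid <- function(record) {
  fs <- record$sample_rate_hz
  per_min <- round(60 * fs)
  t0 <- ceiling(record$time[1] / 60) * 60
  idx_all <- floor((record$time - t0) / 60 + 1e-9)
  n_min <- floor((record$time[length(record$time)] + 1 / fs - t0) / 60 + 1e-9)
  keep <- idx_all >= 0 & idx_all < n_min
  list(t0 = t0, n_min = as.integer(n_min), keep = keep,
       minute = as.integer(idx_all[keep]) + 1L, per_min = per_min,
       starts = t0 + (seq_len(n_min) - 1L) * 60)
}

#' Detect non-wear minutes
#'
#' A minute is stationary when all three per-axis standard deviations within
#' it are at or below `stationarity_sd_g`; maximal runs of stationary
#' minutes of at least `min_duration_minutes` are flagged non-wear.
#'
#' @param record A [triaxial_record()].
#' @param params A [nonwear_params()].
#' @return Logical vector, one element per complete minute of the record
#'   (minute start times in attribute `epoch_start`).
#' @export
detect_nonwear <- function(record, params = nonwear_params()) {
  mg <- minute_grid(record)
  if (mg$n_min < 1L) {
    return(structure(logical(0), epoch_start = numeric(0)))
  }
  axis_sd <- function(a) {
    a <- a[mg$keep]
    n_i <- tabulate(mg$minute, nbins = mg$n_min)
    s1 <- unname(rowsum(a, mg$minute)[, 1])
    s2 <- unname(rowsum(a^2, mg$minute)[, 1])
    sqrt(pmax(s2 - s1^2 / n_i, 0) / pmax(n_i - 1, 1))
  }
  stationary <- axis_sd(record$x) <= params$stationarity_sd_g &
    axis_sd(record$y) <= params$stationarity_sd_g &
    axis_sd(record$z) <= params$stationarity_sd_g
  mask <- logical(mg$n_min)
  r <- rle(stationary)
  ends <- cumsum(r$lengths)
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] >= params$min_duration_minutes) {
      mask[(ends[i] - r$lengths[i] + 1L):ends[i]] <- TRUE
    }
  }
  structure(mask, epoch_start = mg$starts)
}

# Merge candidate runs separated by <= join_gap, keep blocks >= min_block.
join_candidate_runs <- function(candidate, join_gap, min_block) {
  mask <- logical(length(candidate))
  r <- rle(candidate)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0L) return(mask)
  blocks <- list(c(starts[runs[1]], ends[runs[1]]))
  for (ri in runs[-1]) {
    last <- blocks[[length(blocks)]]
    if (starts[ri] - last[2] - 1L <= join_gap) {
      blocks[[length(blocks)]] <- c(last[1], ends[ri])
    } else {
      blocks[[length(blocks) + 1L]] <- c(starts[ri], ends[ri])
    }
  }
  for (b in blocks) {
    if (b[2] - b[1] + 1L >= min_block) mask[b[1]:b[2]] <- TRUE
  }
  mask
}

#' Detect sleep minutes
#'
#' Two stages: (1) candidate minutes whose ROCAM epoch value is below
#' `candidate_threshold` and for which at least `quiet_fraction` of the
#' minute's 1-second mean-ROCAM sub-windows are below the threshold;
#' (2) candidate segments separated by at most `join_gap_minutes` are
#' joined, and joined blocks of at least `min_block_minutes` are accepted.
#' Non-wear minutes are never sleep.
#'
#' @param record A [triaxial_record()].
#' @param epochs_rocam Optional precomputed ROCAM [epoch_series()] on the
#'   record's minute grid (computed from the record when `NULL`).
#' @param params A [sleep_params()].
#' @param nonwear_mask Optional logical minute mask from [detect_nonwear()].
#' @return Logical minute mask with attribute `epoch_start`, and attribute
#'   `blocks` (data.frame of sleep onset/offset times, the first/last minute
#'   of each block).
#' @export
detect_sleep <- function(record, epochs_rocam = NULL, params = sleep_params(),
                         nonwear_mask = NULL) {
  mg <- minute_grid(record)
  roc <- rocam(record)
  if (is.null(epochs_rocam)) epochs_rocam <- epoch_aggregate(roc)
  ep_t <- epochs_rocam$epoch_start
  if (length(ep_t) != mg$n_min || (mg$n_min > 0L && any(ep_t != mg$starts))) {
    stop_wristpa("ROCAM epochs are not on the record's minute grid",
                 "alignment_error")
  }
  if (!is.null(nonwear_mask) && length(nonwear_mask) != mg$n_min) {
    stop_wristpa("non-wear mask length does not match the minute grid",
                 "alignment_error")
  }
  # 1-second mean ROCAM, then per-minute quiet fraction
  sec_idx <- floor((roc$time - mg$t0) + 1e-9)
  keep <- sec_idx >= 0 & sec_idx < mg$n_min * 60L
  sec_means <- group_means(roc$values[keep], as.integer(sec_idx[keep]) + 1L,
                           mg$n_min * 60L)
  quiet <- sec_means < params$candidate_threshold
  minute_of_sec <- rep(seq_len(mg$n_min), each = 60L)
  quiet_frac <- group_means(as.numeric(quiet), minute_of_sec, mg$n_min)
  candidate <- !is.na(epochs_rocam$values) &
    epochs_rocam$values < params$candidate_threshold &
    !is.na(quiet_frac) & quiet_frac >= params$quiet_fraction
  if (!is.null(nonwear_mask)) candidate <- candidate & !nonwear_mask
  mask <- join_candidate_runs(candidate, params$join_gap_minutes,
                              params$min_block_minutes)
  if (!is.null(nonwear_mask)) mask <- mask & !nonwear_mask
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  blocks <- data.frame(onset = mg$starts[starts[on]],
                       offset = mg$starts[ends[on]])
  structure(mask, epoch_start = mg$starts, blocks = blocks)
}
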