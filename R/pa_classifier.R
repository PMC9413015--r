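#' @title Threshold-based activity classification
#' @name pa_classifier
#' @description Maps per-minute summary-measure values to the five activity
#'   categories through four ordered cut-points. Bands are half-open with
#'   inclusive upper bounds (`lower < x <= upper`); values at or below the
#'   sleep floor are sleep, and values above the moderate/vigorous cut are
#'   vigorous. Precedence per minute: non-wear mask, then sleep mask, then
#'   the value bands.
NULL

#' Construct a threshold set
#'
#' @param measure One of `enmonz`, `mad`, `ai`, `rocam`.
#' @param sample_rate_hz Rate the thresholds were derived at.
#' @param sleep_floor,sed_light,light_mod,mod_vig The four ordered
#'   cut-points (same units as the measure), strictly increasing and
#'   positive.
#' @return A `threshold_set` object.
#' @export
threshold_set <- function(measure, sample_rate_hz, sleep_floor, sed_light,
                          light_mod, mod_vig) {
  measure <- match.arg(tolower(measure), c("enmonz", "mad", "ai", "rocam"))
  cuts <- c(sleep_floor, sed_light, light_mod, mod_vig)
  if (any(!is.finite(cuts)) || sleep_floor <= 0 || any(diff(cuts) <= 0)) {
    stop_wristpa("cut-points must satisfy 0 < sleep_floor < sed_light < light_mod < mod_vig",
                 "config_error")
  }
  structure(list(measure = measure, sample_rate_hz = sample_rate_hz,
                 sleep_floor = sleep_floor, sed_light = sed_light,
                 light_mod = light_mod, mod_vig = mod_vig),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "<threshold_set> %s @ %g Hz: sleep<=%.4g < sedentary <=%.4g < light <=%.4g < moderate <=%.4g < vigorous\n",
    x$measure, x$sample_rate_hz, x$sleep_floor, x$sed_light, x$light_mod,
    x$mod_vig))
  invisible(x)
}

# Default cut-points for 10 Hz data, per measure.
DEFAULT_THRESHOLDS_10HZ <- list(
  enmonz = c(1e-4, 0.032, 0.173, 0.382),
  mad = c(0.001, 0.059, 0.242, 0.38),
  ai = c(0.010, 5.308, 17.010, 23.628),
  rocam = c(0.06, 0.175, 0.400, 0.483)
)

#' Default thresholds for 10 Hz data
#'
#' Returns the package's default cut-points for one measure, derived for
#' data sampled at 10 Hz. The published ENMONZ sedentary band starts at 0;
#' since a `threshold_set` requires a strictly positive sleep floor, the
#' ENMONZ floor is represented as 1e-4 g (any awake minute with ENMONZ at or
#' below 0.1 mg is indistinguishable from rest at that scale).
#'
#' @param measure One of `enmonz`, `mad`, `ai`, `rocam`.
#' @return A [threshold_set()].
#' @export
default_thresholds <- function(measure) {
  measure <- tolower(measure)
  if (!measure %in% names(DEFAULT_THRESHOLDS_10HZ)) {
    stop_wristpa(paste0("no default thresholds for measure '", measure, "'"),
                 "config_error")
  }
  cc <- DEFAULT_THRESHOLDS_10HZ[[measure]]
  threshold_set(measure, 10, cc[1], cc[2], cc[3], cc[4])
}

#' Classify epochs into the five categories
#'
#' @param epochs An [epoch_series()].
#' @param thresholds A [threshold_set()] for the same measure; a rate
#'   mismatch between epochs and thresholds triggers a loud warning because
#'   cut-points are sample-rate specific.
#' @param sleep_mask,nonwear_mask Optional logical minute masks on the same
#'   grid (e.g. from [detect_sleep()] / [detect_nonwear()]).
#' @return A [label_series()]. Precedence: non-wear, then sleep mask, then
#'   value bands (value <= sleep floor is sleep); unknown epochs stay
#'   unknown.
#' @export
classify_epochs <- function(epochs, thresholds, sleep_mask = NULL,
                            nonwear_mask = NULL) {
  stopifnot(inherits(epochs, "epoch_series"),
            inherits(thresholds, "threshold_set"))
  if (epochs$measure != thresholds$measure) {
    stop_wristpa(sprintf("thresholds are for %s but epochs are %s",
                         thresholds$measure, epochs$measure), "config_error")
  }
  if (!is.na(epochs$sample_rate_hz) && !is.na(thresholds$sample_rate_hz) &&
      epochs$sample_rate_hz != thresholds$sample_rate_hz) {
    warn_wristpa(sprintf(
      "thresholds derived at %g Hz applied to %g Hz epochs; cut-points are sample-rate specific",
      thresholds$sample_rate_hz, epochs$sample_rate_hz), "rate_mismatch")
  }
  n <- length(epochs$values)
  for (m in list(sleep_mask, nonwear_mask)) {
    if (!is.null(m) && length(m) != n) {
      stop_wristpa("mask length does not match the epoch grid",
                   "alignment_error")
    }
  }
  cuts <- c(thresholds$sleep_floor, thresholds$sed_light,
            thresholds$light_mod, thresholds$mod_vig)
  # bands are (lower, upper]; findInterval with left.open gives exactly that
  band <- findInterval(epochs$values, cuts, left.open = TRUE) + 1L
  cat_chr <- PA_LEVELS[pmin(band, 5L)]
  cat_chr[is.na(epochs$values)] <- "unknown"
  if (!is.null(sleep_mask)) cat_chr[sleep_mask] <- "sleep"
  if (!is.null(nonwear_mask)) cat_chr[nonwear_mask] <- "nonwear"
  label_series(epochs$epoch_start, cat_chr)
}

#' Classify all four measures on a shared grid
#'
#' @param epoch_list Named list of [epoch_series()] (as from
#'   [summarize_record()]).
#' @param thresholds_list Named list of [threshold_set()], one per measure.
#' @param sleep_mask,nonwear_mask Optional shared minute masks.
#' @return Named list of [label_series()], one per measure, with identical
#'   sleep/non-wear handling across measures.
#' @export
classify_all_measures <- function(epoch_list, thresholds_list,
                                  sleep_mask = NULL, nonwear_mask = NULL) {
  grids <- lapply(epoch_list, `[[`, "epoch_start")
  if (length(grids) > 1L &&
      !all(vapply(grids[-1], function(g) identical(g, grids[[1]]), logical(1)))) {
    stop_wristpa("epoch series are on different grids", "alignment_error")
  }
  setNames(lapply(names(epoch_list), function(m) {
    classify_epochs(epoch_list[[m]], thresholds_list[[m]], sleep_mask,
                    nonwear_mask)
  }), names(epoch_list))
}

#' Read a threshold configuration CSV
#'
#' File columns: `measure, rate_hz, sleep_floor, sed_light, light_mod,
#' mod_vig`. The package ships its 10 Hz defaults at
#' `system.file("extdata", "thresholds_10hz.csv", package = "wristpa")`.
#'
#' @param path File path.
#' @return Named list of [threshold_set()] keyed by measure.
#' @export
read_thresholds <- function(path) {
  dt <- data.table::fread(path, showProgress = FALSE)
  need <- c("measure", "rate_hz", "sleep_floor", "sed_light", "light_mod",
            "mod_vig")
  if (!all(need %in% names(dt))) {
    stop_wristpa(paste0("threshold file needs columns: ",
                        paste(need, collapse = ",")), "format_error")
  }
  out <- lapply(seq_len(nrow(dt)), function(i) {
    threshold_set(dt$measure[i], dt$rate_hz[i], dt$sleep_floor[i],
                  dt$sed_light[i], dt$light_mod[i], dt$mod_vig[i])
  })
  setNames(out, tolower(dt$measure))
}

#' Full single-day profiling pipeline
#'
#' Convenience wrapper: summary measure, non-wear and sleep masks, and
#' threshold classification for one record.
#'
#' @param record A [triaxial_record()].
#' @param measure Measure used for classification (default `rocam`).
#' @param thresholds A [threshold_set()] (default: 10 Hz defaults for the
#'   measure).
#' @param sleep_pars A [sleep_params()].
#' @param nonwear_pars A [nonwear_params()].
#' @param config A [measure_config()].
#' @return List with `labels` (a [label_series()]), `epochs`, `sleep_mask`,
#'   and `nonwear_mask`.
#' @export
profile_day <- function(record, measure = "rocam",
                        thresholds = default_thresholds(measure),
                        sleep_pars = sleep_params(),
                        nonwear_pars = nonwear_params(),
                        config = measure_config()) {
  nonwear <- detect_nonwear(record, nonwear_pars)
  roc_ep <- epoch_aggregate(rocam(record, config), config$epoch_seconds)
  sleep <- detect_sleep(record, roc_ep, sleep_pars, as.logical(nonwear))
  epochs <- if (measure == "rocam") roc_ep else
    summarize_record(record, measure, config)[[measure]]
  labels <- classify_epochs(epochs, thresholds, as.logical(sleep),
                            as.logical(nonwear))
  list(labels = labels, epochs = epochs, sleep_mask = sleep,
       nonwear_mask = nonwear)
}
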