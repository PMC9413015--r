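#' @title Reading and writing tri-axial acceleration streams and epoch tables
#' @name signal_io
#' @description Delimited-text input/output for raw tri-axial acceleration
#'   (columns `time,x,y,z`, units g), per-minute epoch tables, and per-minute
#'   activity labels. Epochs are labeled by their start minute and cover the
#'   half-open interval `[start, start + 60 s)`.
NULL

# The five ordered physical-activity categories plus the two sentinels.
PA_LEVELS <- c("sleep", "sedentary", "light", "moderate", "vigorous")
ALL_LEVELS <- c(PA_LEVELS, "nonwear", "unknown")

#' Construct a tri-axial acceleration record
#'
#' Container for a raw wrist-acceleration stream: per-sample timestamps
#' (seconds since stream start), the three axes in gravitational units (g),
#' the nominal sample rate, and the sensor dynamic range. Samples outside
#' the dynamic range are clipped to +/- `dynamic_range_g` (sign preserved)
#' and counted in a warning, so the sample grid stays intact.
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y,z Numeric vectors of per-axis acceleration in g.
#' @param sample_rate_hz Nominal sample rate in Hz.
#' @param dynamic_range_g Absolute bound on acceleration (default 8 g, the
#'   range of common research-grade wrist sensors).
#' @param jitter_tol Allowed relative deviation of successive timestamp gaps
#'   from `1/sample_rate_hz` (default 0.1).
#' @return An object of class `triaxial_record`.
#' @export
triaxial_record <- function(time, x, y, z, sample_rate_hz,
                            dynamic_range_g = 8, jitter_tol = 0.1) {
  n <- length(time)
  if (n < 2L || length(x) != n || length(y) != n || length(z) != n) {
    stop_wristpa("time, x, y, z must have identical length >= 2", "data_error")
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    stop_wristpa("timestamps must be strictly increasing", "data_error")
  }
  step <- 1 / sample_rate_hz
  if (any(abs(dt - step) > jitter_tol * step)) {
    stop_wristpa(sprintf(
      "timestamp gaps deviate from 1/%g s by more than %g%%",
      sample_rate_hz, 100 * jitter_tol), "data_error")
  }
  clip <- function(a) pmin(pmax(a, -dynamic_range_g), dynamic_range_g)
  n_clip <- sum(abs(x) > dynamic_range_g) + sum(abs(y) > dynamic_range_g) +
    sum(abs(z) > dynamic_range_g)
  if (n_clip > 0L) {
    x <- clip(x); y <- clip(y); z <- clip(z)
    warn_wristpa(sprintf(
      "%d sample value(s) outside +/-%g g were clipped", n_clip,
      dynamic_range_g), "clip")
  }
  structure(
    list(time = as.numeric(time), x = as.numeric(x), y = as.numeric(y),
         z = as.numeric(z), sample_rate_hz = sample_rate_hz,
         dynamic_range_g = dynamic_range_g),
    class = "triaxial_record"
  )
}

#' @export
print.triaxial_record <- function(x, ...) {
  cat(sprintf(
    "<triaxial_record> %d samples @ %g Hz (%.1f min), range +/-%g g\n",
    length(x$time), x$sample_rate_hz, diff(range(x$time)) / 60,
    x$dynamic_range_g))
  invisible(x)
}

#' Construct an epoch series of one summary measure
#'
#' One value per 1-minute epoch for one acceleration summary measure.
#' `NA` values mark epochs flagged `unknown` (partial raw data).
#'
#' @param epoch_start Numeric vector of epoch start times (seconds),
#'   minute-aligned and strictly increasing in steps of 60 s (gaps allowed).
#' @param values Non-negative numeric values, one per epoch (`NA` = unknown).
#' @param measure One of `"enmonz"`, `"mad"`, `"ai"`, `"rocam"`.
#' @param sample_rate_hz Sample rate of the stream the epochs came from
#'   (used to guard against applying thresholds across rates).
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(epoch_start, values, measure,
                         sample_rate_hz = NA_real_) {
  measure <- match.arg(tolower(measure), c("enmonz", "mad", "ai", "rocam"))
  if (length(epoch_start) != length(values)) {
    stop_wristpa("epoch_start and values differ in length", "data_error")
  }
  if (length(epoch_start) > 1L) {
    gaps <- diff(epoch_start)
    if (any(gaps <= 0) || any(abs(gaps %% 60) > 1e-6 & abs(60 - gaps %% 60) > 1e-6)) {
      stop_wristpa("epoch_start must increase in multiples of 60 s", "data_error")
    }
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop_wristpa("summary-measure values must be non-negative", "data_error")
  }
  structure(
    list(epoch_start = as.numeric(epoch_start), values = as.numeric(values),
         measure = measure, epoch_seconds = 60,
         sample_rate_hz = sample_rate_hz),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %s: %d one-minute epochs (%d unknown)\n",
              x$measure, length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Construct a per-minute activity label series
#'
#' @param epoch_start Numeric vector of minute-aligned epoch start times (s).
#' @param category Character or factor with levels among `sleep`,
#'   `sedentary`, `light`, `moderate`, `vigorous`, `nonwear`, `unknown`.
#' @return An object of class `label_series`. The five activity categories
#'   carry ordinal codes 0 (sleep) through 4 (vigorous); `nonwear` and
#'   `unknown` are sentinels outside the ordinal scale.
#' @export
label_series <- function(epoch_start, category) {
  if (length(epoch_start) != length(category)) {
    stop_wristpa("epoch_start and category differ in length", "data_error")
  }
  cat_chr <- tolower(as.character(category))
  cat_chr[cat_chr %in% c("non-wear", "non_wear")] <- "nonwear"
  bad <- setdiff(unique(cat_chr), ALL_LEVELS)
  if (length(bad) > 0L) {
    stop_wristpa(paste0("unknown category value(s): ",
                        paste(bad, collapse = ", ")), "format_error")
  }
  structure(
    list(epoch_start = as.numeric(epoch_start),
         category = factor(cat_chr, levels = ALL_LEVELS)),
    class = "label_series"
  )
}

#' @export
print.label_series <- function(x, ...) {
  tb <- table(x$category)
  cat(sprintf("<label_series> %d minutes: %s\n", length(x$category),
              paste(sprintf("%s=%d", names(tb)[tb > 0], tb[tb > 0]),
                    collapse = " ")))
  invisible(x)
}

#' Ordinal codes of a label series
#'
#' @param labels A [label_series()].
#' @return Integer vector: sleep=0, sedentary=1, light=2, moderate=3,
#'   vigorous=4; `NA` for `nonwear`/`unknown`.
#' @export
pa_code <- function(labels) {
  code <- match(as.character(labels$category), PA_LEVELS) - 1L
  code
}

parse_time_column <- function(tm) {
  if (is.numeric(tm)) return(as.numeric(tm))
  tt <- suppressWarnings(as.numeric(tm))
  if (!anyNA(tt)) return(tt)
  ps <- as.POSIXct(tm, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ps)) {
    stop_wristpa("time column is neither numeric seconds nor ISO-8601",
                 "format_error")
  }
  as.numeric(ps) - as.numeric(ps[1])
}

#' Read a raw tri-axial stream from CSV
#'
#' Expects a header row with columns `time,x,y,z`; time is either float
#' seconds or ISO-8601 (auto-detected), accelerations in g.
#'
#' @param path File path.
#' @param sample_rate_hz Nominal sample rate of the file in Hz.
#' @param dynamic_range_g Sensor range; out-of-range values are clipped.
#' @return A [triaxial_record()].
#' @export
read_triaxial <- function(path, sample_rate_hz, dynamic_range_g = 8) {
  dt <- data.table::fread(path, showProgress = FALSE)
  need <- c("time", "x", "y", "z")
  if (!all(need %in% tolower(names(dt)))) {
    stop_wristpa(paste0("file must have columns time,x,y,z; found: ",
                        paste(names(dt), collapse = ",")), "format_error")
  }
  names(dt) <- tolower(names(dt))
  if (nrow(dt) < 2L) {
    stop_wristpa("fewer than 2 samples in file", "data_error")
  }
  tm <- parse_time_column(dt$time)
  if (any(diff(tm) <= 0)) {
    stop_wristpa("time column is not strictly increasing", "data_error")
  }
  triaxial_record(tm, dt$x, dt$y, dt$z, sample_rate_hz = sample_rate_hz,
                  dynamic_range_g = dynamic_range_g)
}

#' Write a tri-axial stream to CSV
#'
#' @param record A [triaxial_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_triaxial <- function(record, path) {
  data.table::fwrite(
    data.table::data.table(time = record$time, x = record$x, y = record$y,
                           z = record$z),
    path)
  invisible(path)
}

#' Write epoch series (and optional labels) to CSV
#'
#' One row per minute, one column per measure plus an optional `label`
#' column; values round-trip losslessly through [read_epochs()].
#'
#' @param series A single [epoch_series()] or a list of them sharing one
#'   epoch grid.
#' @param path Output file path.
#' @param labels Optional [label_series()] on the same grid.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(series, path, labels = NULL) {
  if (inherits(series, "epoch_series")) series <- list(series)
  grids <- lapply(series, `[[`, "epoch_start")
  if (length(grids) > 1L) {
    same <- vapply(grids[-1], function(g) {
      length(g) == length(grids[[1]]) && all(g == grids[[1]])
    }, logical(1))
    if (!all(same)) {
      stop_wristpa("epoch series are on different epoch grids",
                   "alignment_error")
    }
  }
  if (!is.null(labels)) {
    if (length(labels$epoch_start) != length(grids[[1]]) ||
        (length(grids[[1]]) > 0L && !all(labels$epoch_start == grids[[1]]))) {
      stop_wristpa("label series is on a different epoch grid",
                   "alignment_error")
    }
  }
  out <- data.table::data.table(time = grids[[1]])
  for (s in series) out[[s$measure]] <- s$values
  if (!is.null(labels)) out[["label"]] <- as.character(labels$category)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read an epoch table written by [write_epochs()]
#'
#' @param path File path.
#' @param sample_rate_hz Optional rate tag to attach to the series.
#' @return Named list of [epoch_series()] (one per measure column), plus a
#'   `labels` element when a `label` column is present.
#' @export
read_epochs <- function(path, sample_rate_hz = NA_real_) {
  dt <- data.table::fread(path, showProgress = FALSE)
  if (!"time" %in% names(dt)) {
    stop_wristpa("epoch file must have a time column", "format_error")
  }
  tm <- parse_time_column(dt$time)
  out <- list()
  for (nm in intersect(names(dt), c("enmonz", "mad", "ai", "rocam"))) {
    out[[nm]] <- epoch_series(tm, dt[[nm]], nm, sample_rate_hz)
  }
  if ("label" %in% names(dt)) out$labels <- label_series(tm, dt$label)
  out
}

#' Read per-minute labels from CSV
#'
#' Expects columns `time,category` with category names from the
#' five-category set (case-insensitive; `nonwear`/`unknown` sentinels also
#' accepted).
#'
#' @param path File path.
#' @return A [label_series()] (empty for an empty file).
#' @export
read_labels <- function(path) {
  dt <- data.table::fread(path, showProgress = FALSE)
  if (nrow(dt) == 0L) {
    return(label_series(numeric(0), character(0)))
  }
  if (!all(c("time", "category") %in% tolower(names(dt)))) {
    stop_wristpa("label file must have columns time,category", "format_error")
  }
  names(dt) <- tolower(names(dt))
  label_series(parse_time_column(dt$time), dt$category)
}

#' Write per-minute labels to CSV
#'
#' @param labels A [label_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  data.table::fwrite(
    data.table::data.table(time = labels$epoch_start,
                           category = as.character(labels$category)),
    path)
  invisible(path)
}
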