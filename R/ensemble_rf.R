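#' @title Random-forest fusion of per-measure estimates
#' @name ensemble_rf
#' @description Combines the four per-measure category estimates (and/or
#'   the four raw summary-measure values) with a random forest: 500 trees,
#'   candidate features per split equal to the floored square root of the
#'   input dimensionality. Categorical estimate inputs are one-of-k encoded
#'   (5 categories x 4 measures = 20 columns in estimates-only mode). Sleep
#'   and non-wear minutes keep their mask precedence: the forest only
#'   re-labels awake, worn minutes.
NULL

#' Random-forest combiner configuration
#'
#' @param n_trees Number of trees (default 500).
#' @param seed RNG seed, fixed for reproducibility (default 1).
#' @param input_mode One of `"estimates"`, `"measures"`, `"both"`.
#'   Estimates-only is the default (the computationally simplest of the
#'   three, with combined performance similar to the richer inputs).
#' @param class_weights Optional named class-weight vector (default none;
#'   threshold precedence already limits class dominance).
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 500, seed = 1L,
                      input_mode = c("estimates", "measures", "both"),
                      class_weights = NULL) {
  if (n_trees < 1) stop_wristpa("n_trees must be >= 1", "config_error")
  structure(list(n_trees = as.integer(n_trees), seed = as.integer(seed),
                 input_mode = match.arg(input_mode),
                 class_weights = class_weights),
            class = "rf_config")
}

# One-of-k encode a list of label_series into a 5 x n_measures column
# matrix; raw measures contribute one numeric column each.
encode_inputs <- function(estimates = NULL, measures = NULL, mode) {
  cols <- list()
  if (mode %in% c("estimates", "both")) {
    if (is.null(estimates)) {
      stop_wristpa("input_mode requires category estimates", "config_error")
    }
    for (nm in names(estimates)) {
      f <- factor(as.character(estimates[[nm]]$category), levels = PA_LEVELS)
      for (lv in PA_LEVELS) {
        cols[[paste(nm, lv, sep = "_")]] <- as.numeric(f == lv)
      }
    }
  }
  if (mode %in% c("measures", "both")) {
    if (is.null(measures)) {
      stop_wristpa("input_mode requires raw measure values", "config_error")
    }
    for (nm in names(measures)) {
      cols[[paste0("value_", nm)]] <- measures[[nm]]$values
    }
  }
  do.call(cbind, cols)
}

#' Fit the random-forest combiner
#'
#' @param labels Training [label_series()] (ground truth per minute).
#' @param estimates Named list of per-measure [label_series()] (threshold
#'   estimates), required for `estimates`/`both` modes.
#' @param measures Named list of per-measure [epoch_series()], required for
#'   `measures`/`both` modes.
#' @param config An [rf_config()].
#' @return An `rf_combiner` object recording the input mode and encoding.
#' @export
fit_combiner <- function(labels, estimates = NULL, measures = NULL,
                         config = rf_config()) {
  x <- encode_inputs(estimates, measures, config$input_mode)
  grid <- labels$epoch_start
  srcs <- c(estimates, measures)
  for (s in srcs) {
    if (length(s$epoch_start) != length(grid) || !all(s$epoch_start == grid)) {
      stop_wristpa("combiner inputs and labels are on different grids",
                   "alignment_error")
    }
  }
  y <- factor(as.character(labels$category), levels = PA_LEVELS)
  keep <- !is.na(y) & stats::complete.cases(x)
  if (length(unique(y[keep])) < 2L) {
    stop_wristpa("training labels contain fewer than 2 classes", "data_error")
  }
  y <- droplevels(y[keep])
  mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(config$seed)
  fit <- randomForest::randomForest(
    x = x[keep, , drop = FALSE], y = y,
    ntree = config$n_trees, mtry = mtry,
    classwt = config$class_weights)
  structure(list(fit = fit, input_mode = config$input_mode,
                 feature_names = colnames(x), mtry = mtry,
                 config = config),
            class = "rf_combiner")
}

#' @export
print.rf_combiner <- function(x, ...) {
  cat(sprintf("<rf_combiner> mode=%s, %d trees, %d features (mtry=%d)\n",
              x$input_mode, x$config$n_trees, length(x$feature_names),
              x$mtry))
  invisible(x)
}

#' Predict minute categories with a fitted combiner
#'
#' @param combiner An `rf_combiner` from [fit_combiner()].
#' @param estimates,measures Inputs matching the combiner's `input_mode`.
#' @param sleep_mask,nonwear_mask Optional minute masks; masked minutes pass
#'   through as `sleep`/`nonwear` unchanged.
#' @return A [label_series()].
#' @export
predict_combiner <- function(combiner, estimates = NULL, measures = NULL,
                             sleep_mask = NULL, nonwear_mask = NULL) {
  mode <- combiner$input_mode
  if ((mode %in% c("estimates", "both")) && is.null(estimates)) {
    stop_wristpa("combiner was fitted on category estimates; none supplied",
                 "config_error")
  }
  if ((mode %in% c("measures", "both")) && is.null(measures)) {
    stop_wristpa("combiner was fitted on raw measure values; none supplied",
                 "config_error")
  }
  if (mode == "estimates" && is.null(estimates) == FALSE && !is.null(measures)) {
    stop_wristpa("combiner was fitted in estimates-only mode; raw values are not valid inputs",
                 "config_error")
  }
  x <- encode_inputs(estimates, measures, mode)
  if (!identical(colnames(x), combiner$feature_names)) {
    stop_wristpa("prediction inputs do not match the fitted feature encoding",
                 "config_error")
  }
  grid <- if (!is.null(estimates)) estimates[[1]]$epoch_start else
    measures[[1]]$epoch_start
  pred <- rep(NA_character_, nrow(x))
  ok <- stats::complete.cases(x)
  pred[ok] <- as.character(predict(combiner$fit, x[ok, , drop = FALSE]))
  pred[is.na(pred)] <- "unknown"
  if (!is.null(sleep_mask)) pred[sleep_mask] <- "sleep"
  if (!is.null(nonwear_mask)) pred[nonwear_mask] <- "nonwear"
  label_series(grid, pred)
}

#' Leave-one-participant-out run over all measures plus the RF combiner
#'
#' Per fold: thresholds are optimized independently for each of the four
#' measures on the training participants; the training estimates feed the
#' random-forest combiner; both the per-measure threshold estimates and the
#' combined estimates are evaluated on the held-out participant. Pooled
#' confusion matrices are the element-wise sums over folds.
#'
#' @param cohort List of participants, each a list with `epoch_list` (named
#'   list of four [epoch_series()]) and `labels`.
#' @param spec An [optimizer_spec()].
#' @param config An [rf_config()].
#' @return List with `per_measure` (pooled `pa_confusion` per measure),
#'   `rf_pooled` (pooled combiner matrix), corresponding accuracies, and
#'   `folds` details.
#' @export
lopo_run_multi <- function(cohort, spec = optimizer_spec(),
                           config = rf_config()) {
  N <- length(cohort)
  if (N < 2L) {
    stop_wristpa("leave-one-participant-out needs >= 2 participants",
                 "config_error")
  }
  measures <- names(cohort[[1]]$epoch_list)
  cat_all <- function(parts, m) {
    off <- 0
    out_t <- c(); out_v <- c(); out_l <- character(0)
    for (p in parts) {
      e <- p$epoch_list[[m]]
      out_t <- c(out_t, e$epoch_start + off)
      out_v <- c(out_v, e$values)
      out_l <- c(out_l, as.character(p$labels$category))
      off <- off + max(e$epoch_start) + 60
    }
    list(epochs = epoch_series(out_t, out_v, m,
                               cohort[[1]]$epoch_list[[m]]$sample_rate_hz),
         labels = label_series(out_t, out_l))
  }
  folds <- lapply(seq_len(N), function(i) {
    train <- cohort[-i]
    ths <- list(); est_train <- list(); est_test <- list()
    for (m in measures) {
      tr <- cat_all(train, m)
      fit <- optimize_thresholds(tr$epochs, tr$labels, spec)
      ths[[m]] <- fit$thresholds
      est_train[[m]] <- suppressWarnings(
        classify_epochs(tr$epochs, fit$thresholds))
      est_test[[m]] <- suppressWarnings(
        classify_epochs(cohort[[i]]$epoch_list[[m]], fit$thresholds))
    }
    tr_labels <- cat_all(train, measures[1])$labels
    comb <- fit_combiner(tr_labels, estimates = est_train, config = config)
    rf_est <- predict_combiner(comb, estimates = est_test)
    cms <- lapply(measures, function(m) confusion(cohort[[i]]$labels,
                                                  est_test[[m]]))
    names(cms) <- measures
    list(thresholds = ths, confusions = cms,
         rf_confusion = confusion(cohort[[i]]$labels, rf_est))
  })
  per_measure <- setNames(lapply(measures, function(m) {
    Reduce(`+`, lapply(folds, function(f) f$confusions[[m]]))
  }), measures)
  rf_pooled <- Reduce(`+`, lapply(folds, `[[`, "rf_confusion"))
  list(per_measure = per_measure,
       per_measure_accuracy = vapply(per_measure, accuracy, numeric(1)),
       rf_pooled = rf_pooled, rf_accuracy = accuracy(rf_pooled),
       folds = folds)
}
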