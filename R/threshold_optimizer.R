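#' @title Threshold learning
#' @name threshold_optimizer
#' @description Learns the ordered cut-points of a [threshold_set()] from
#'   labeled epochs: kernel density estimation with diffusion-based
#'   bandwidth selection provides the stratified densities, adjacent-class
#'   density valleys provide the initialization, and a bounded
#'   derivative-free coordinate search maximizes pooled minute-wise accuracy
#'   over the four awake activity levels (sleep and non-wear minutes are
#'   excluded from the objective). A leave-one-participant-out harness
#'   evaluates generalization.
NULL

# --- discrete cosine transforms used by the diffusion KDE ----------------

dct1d <- function(x) {
  n <- length(x)
  w <- c(1, 2 * exp(-1i * (1:(n - 1)) * pi / (2 * n)))
  xr <- c(x[seq(1, n, by = 2)], x[seq(2 * (n %/% 2), 2, by = -2)])
  Re(w * stats::fft(xr))
}

idct1d <- function(a) {
  n <- length(a)
  w <- exp(1i * (0:(n - 1)) * pi / (2 * n))
  y <- Re(stats::fft(w * a, inverse = TRUE)) / n
  out <- numeric(n)
  out[seq(1, n, by = 2)] <- y[1:(n %/% 2 + n %% 2)]
  out[seq(2, n, by = 2)] <- y[n:(n %/% 2 + 1)]
  out
}

# Fixed-point function of the diffusion bandwidth selection: t maps to the
# squared bandwidth implied by the l-stage plug-in functional estimates.
kde_fixed_point <- function(t, N, I2, a2) {
  l <- 7
  f <- 2 * pi^(2 * l) * sum(I2^l * a2 * exp(-I2 * pi^2 * t))
  for (s in seq(l - 1, 2)) {
    K0 <- prod(seq(1, 2 * s - 1, by = 2)) / sqrt(2 * pi)
    const <- (1 + (1 / 2)^(s + 1 / 2)) / 3
    tt <- (2 * const * K0 / (N * f))^(2 / (3 + 2 * s))
    f <- 2 * pi^(2 * s) * sum(I2^s * a2 * exp(-I2 * pi^2 * tt))
  }
  (2 * N * sqrt(pi) * f)^(-2 / 5)
}

#' Kernel density estimate with diffusion bandwidth selection
#'
#' Gaussian KDE whose bandwidth is chosen by the diffusion fixed-point rule
#' (solving `t = xi * gamma^[5](t)` in the DCT domain), which is markedly
#' less prone to oversmoothing multimodal activity distributions than
#' rule-of-thumb bandwidths.
#'
#' @param values Numeric sample (>= 30 finite values with non-degenerate
#'   spread).
#' @param n_grid Number of grid points (rounded up to a power of 2,
#'   default 2^12).
#' @param range_ext Fractional extension of the data range on both sides
#'   (default 0.1).
#' @return List with `x` (grid), `density` (non-negative, integrates to 1),
#'   and `bandwidth`.
#' @export
kde_diffusion <- function(values, n_grid = 2^12, range_ext = 0.1) {
  values <- values[is.finite(values)]
  N_unique <- length(unique(values))
  if (length(values) < 30L) {
    stop_wristpa("need >= 30 finite values for density estimation",
                 "data_error")
  }
  if (N_unique < 2L || diff(range(values)) <= 0) {
    stop_wristpa("degenerate (constant) sample has no density", "data_error")
  }
  n <- 2^ceiling(log2(n_grid))
  r <- range(values)
  R <- diff(r)
  lo <- r[1] - range_ext * R
  hi <- r[2] + range_ext * R
  RR <- hi - lo
  brk <- seq(lo, hi, length.out = n + 1L)
  bin <- pmin(pmax(findInterval(values, brk, rightmost.closed = TRUE), 1L), n)
  initial <- tabulate(bin, nbins = n) / length(values)
  a <- dct1d(initial)
  I2 <- (1:(n - 1))^2
  a2 <- (a[-1] / 2)^2
  N <- N_unique
  g <- function(t) kde_fixed_point(t, N, I2, a2) - t
  # g is positive near 0 and crosses to negative at the fixed point;
  # scan upward for the sign change, then bisect
  t_star <- NA_real_
  lo_t <- .Machine$double.eps
  g_lo <- tryCatch(g(lo_t), error = function(e) NA_real_)
  for (ub in seq(0.005, 0.2, by = 0.005)) {
    val <- tryCatch(g(ub), error = function(e) NA_real_)
    if (!is.finite(val)) next
    if (is.finite(g_lo) && g_lo > 0 && val < 0) {
      t_star <- tryCatch(uniroot(g, c(lo_t, ub), tol = 1e-12)$root,
                         error = function(e) NA_real_)
      break
    }
    lo_t <- ub
    g_lo <- val
  }
  if (!is.finite(t_star)) t_star <- (0.28 * N^(-2 / 5))^2
  at <- a * exp(-(0:(n - 1))^2 * pi^2 * t_star / 2)
  dens <- idct1d(at) * (n / RR)
  dens <- pmax(dens, 0)
  xg <- brk[-(n + 1L)] + RR / (2 * n)
  dens <- dens / (sum(dens) * RR / n)
  list(x = xg, density = dens, bandwidth = sqrt(t_star) * RR)
}

# Valley between the modes of two class densities evaluated on a shared
# grid; NULL when the modes are not ordered apart.
density_valley <- function(v_lo, v_hi, n_grid = 2^12) {
  pooled <- c(v_lo, v_hi)
  r <- range(pooled[is.finite(pooled)])
  ext <- 0.05 * diff(r)
  grid <- seq(r[1] - ext, r[2] + ext, length.out = n_grid)
  dens_on <- function(v) {
    k <- kde_diffusion(v)
    approx(k$x, k$density, xout = grid, yleft = 0, yright = 0)$y
  }
  d1 <- dens_on(v_lo)
  d2 <- dens_on(v_hi)
  m1 <- grid[which.max(d1)]
  m2 <- grid[which.max(d2)]
  if (m2 <= m1) return(NULL)
  between <- grid > m1 & grid < m2
  if (!any(between)) return(NULL)
  tot <- (d1 + d2)[between]
  # the minimum can sit on a flat near-zero plateau when the classes are
  # widely separated; take the plateau midpoint for a symmetric cut
  flat <- tot <= min(tot) + 1e-9 * max(tot)
  stats::median(grid[between][flat])
}

#' Initialize thresholds from stratified densities
#'
#' For each adjacent category pair (sleep/sedentary through
#' moderate/vigorous) the initial cut is the minimizer of the summed class
#' densities between the two modes. A missing or degenerate pair falls back
#' to the midpoint of that cut's bounds, with a warning.
#'
#' @param stratified Named list mapping category names (subset of the five)
#'   to numeric value samples.
#' @param measure,sample_rate_hz Tags for the returned [threshold_set()].
#' @param bounds Optional 4x2 matrix of per-cut (lower, upper) bounds used
#'   for fallbacks and clipping.
#' @return A [threshold_set()].
#' @export
init_thresholds <- function(stratified, measure = "rocam",
                            sample_rate_hz = NA_real_, bounds = NULL) {
  ok <- vapply(stratified, function(v) sum(is.finite(v)) >= 30L, logical(1))
  if (sum(ok) < 2L) {
    stop_wristpa("need >= 2 categories with >= 30 values each", "data_error")
  }
  pooled <- unlist(stratified, use.names = FALSE)
  pooled <- pooled[is.finite(pooled)]
  if (is.null(bounds)) {
    qs <- quantile(pooled, c(0.001, 0.999), names = FALSE)
    bounds <- matrix(rep(qs, each = 4L), nrow = 4L)
  }
  pairs <- cbind(PA_LEVELS[1:4], PA_LEVELS[2:5])
  cuts <- rep(NA_real_, 4L)
  for (i in 1:4) {
    lo_cat <- pairs[i, 1]; hi_cat <- pairs[i, 2]
    cut <- NULL
    if (!is.null(stratified[[lo_cat]]) && !is.null(stratified[[hi_cat]]) &&
        isTRUE(ok[lo_cat]) && isTRUE(ok[hi_cat])) {
      cut <- tryCatch(
        density_valley(stratified[[lo_cat]], stratified[[hi_cat]]),
        wristpa_error = function(e) NULL)
    }
    if (is.null(cut)) {
      warn_wristpa(sprintf(
        "no separable densities for %s/%s; cut initialized at bound midpoint",
        lo_cat, hi_cat), "init_fallback")
    } else {
      cuts[i] <- min(max(cut, bounds[i, 1]), bounds[i, 2])
    }
  }
  # fallback cuts take the bound midpoint but never push a density-derived
  # cut out of order: they are clamped between their resolved neighbors
  eps <- 1e-9 + 1e-6 * diff(range(pooled))
  for (i in which(is.na(cuts))) {
    nxt <- which(!is.na(cuts) & seq_len(4L) > i)
    upper <- if (length(nxt)) min(cuts[nxt[1]] - eps, bounds[i, 2]) else
      bounds[i, 2]
    lower <- if (i > 1L && !is.na(cuts[i - 1L])) max(cuts[i - 1L] + eps,
                                                     bounds[i, 1]) else
      bounds[i, 1]
    mid <- mean(bounds[i, ])
    cuts[i] <- if (lower <= upper) min(max(mid, lower), upper) else
      mean(c(lower, upper))
  }
  for (i in 2:4) cuts[i] <- max(cuts[i], cuts[i - 1] + eps)
  cuts[1] <- max(cuts[1], eps)
  threshold_set(measure, sample_rate_hz, cuts[1], cuts[2], cuts[3], cuts[4])
}

#' Optimizer specification
#'
#' @param bounds Optional 4x2 matrix of (lower, upper) bounds per cut-point
#'   (rows: sleep floor, sedentary/light, light/moderate,
#'   moderate/vigorous). Default: for each cut, the 5th percentile of the
#'   lower class to the 95th percentile of the upper class, a reproducible
#'   stand-in for visual inspection of the stratified distributions that
#'   also guards against dominance of large classes.
#' @param init A [threshold_set()] or `"auto"` (density-valley
#'   initialization).
#' @param tolerance Minimum objective improvement to continue sweeping
#'   (default 1e-6).
#' @param max_evaluations Cap on objective evaluations (default 5000).
#' @param max_candidates Candidate cut positions per coordinate sweep,
#'   drawn from observed-value quantiles (default 200).
#' @param seed Optional RNG seed (the search itself is deterministic).
#' @return An `optimizer_spec` list.
#' @export
optimizer_spec <- function(bounds = NULL, init = "auto", tolerance = 1e-6,
                           max_evaluations = 5000, max_candidates = 200,
                           seed = NULL) {
  if (!is.null(bounds)) {
    bounds <- as.matrix(bounds)
    if (nrow(bounds) != 4L || ncol(bounds) != 2L ||
        any(bounds[, 2] < bounds[, 1])) {
      stop_wristpa("bounds must be a 4x2 matrix with upper >= lower",
                   "config_error")
    }
  }
  structure(list(bounds = bounds, init = init, tolerance = tolerance,
                 max_evaluations = max_evaluations,
                 max_candidates = max_candidates, seed = seed),
            class = "optimizer_spec")
}

default_cut_bounds <- function(values, code) {
  bounds <- matrix(NA_real_, 4L, 2L)
  qs <- function(k, p) {
    v <- values[code == k]
    if (length(v) < 2L) return(NA_real_)
    quantile(v, p, names = FALSE)
  }
  for (i in 1:4) {
    lo <- qs(i - 1L, 0.05)
    hi <- qs(i, 0.95)
    if (!is.finite(lo)) lo <- min(values)
    if (!is.finite(hi)) hi <- max(values)
    bounds[i, ] <- sort(c(lo, hi))
  }
  bounds
}

# Pooled accuracy of the 4-level banding (codes 1..4) given three PA cuts.
pa_band_accuracy <- function(values, code, cuts3) {
  est <- findInterval(values, cuts3, left.open = TRUE) + 1L
  mean(est == code)
}

#' Optimize a threshold set on labeled epochs
#'
#' Maximizes pooled minute-wise accuracy over the four awake activity
#' levels by a bounded derivative-free coordinate search: the objective is
#' piecewise constant in each cut, so each sweep evaluates candidate cut
#' positions drawn from observed-value quantiles inside the cut's feasible
#' window (bounds intersected with the neighboring cuts), accepting
#' improvements and breaking ties toward the smaller cut. Sleep and
#' non-wear minutes never enter the objective; the sleep floor is kept from
#' the initialization (clipped below the sedentary/light cut).
#'
#' @param epochs An [epoch_series()].
#' @param labels A [label_series()] on the same grid.
#' @param spec An [optimizer_spec()].
#' @return List with `thresholds` (a [threshold_set()]), `accuracy`
#'   (achieved, never below `init_accuracy`), `init_accuracy`, and
#'   `n_evaluations`.
#' @export
optimize_thresholds <- function(epochs, labels, spec = optimizer_spec()) {
  if (length(epochs$epoch_start) != length(labels$epoch_start) ||
      !all(epochs$epoch_start == labels$epoch_start)) {
    stop_wristpa("epochs and labels are on different grids",
                 "alignment_error")
  }
  code <- pa_code(labels)
  keep <- !is.na(code) & !is.na(epochs$values)
  v_all <- epochs$values[keep]
  c_all <- code[keep]
  pa <- c_all >= 1L
  v <- v_all[pa]
  k <- c_all[pa]
  if (length(unique(k)) < 2L) {
    stop_wristpa("labels must contain >= 2 of the four activity levels",
                 "data_error")
  }
  bounds <- spec$bounds %||% default_cut_bounds(v_all, c_all)
  if (any(bounds[, 1] > bounds[, 2])) {
    stop_wristpa("infeasible bounds", "config_error")
  }
  init <- spec$init
  if (identical(init, "auto")) {
    strat <- split(v_all, PA_LEVELS[c_all + 1L])
    init <- suppressWarnings(
      init_thresholds(strat, epochs$measure, epochs$sample_rate_hz, bounds))
  }
  cuts <- c(init$sleep_floor, init$sed_light, init$light_mod, init$mod_vig)
  eps <- 1e-9 + 1e-9 * diff(range(v))
  cuts <- pmin(pmax(cuts, bounds[, 1]), bounds[, 2])
  for (i in 2:4) cuts[i] <- max(cuts[i], cuts[i - 1] + eps)
  n_eval <- 0L
  obj <- function(c3) {
    n_eval <<- n_eval + 1L
    pa_band_accuracy(v, k, c3)
  }
  best <- obj(cuts[2:4])
  init_acc <- best
  qs <- quantile(v, probs = seq(0, 1, length.out = spec$max_candidates),
                 names = FALSE)
  repeat {
    improved <- FALSE
    for (i in 1:3) {
      ci <- i + 1L  # index into the 4-cut vector
      lo <- max(bounds[ci, 1], if (ci > 1L) cuts[ci - 1L] + eps else -Inf)
      hi <- min(bounds[ci, 2], if (ci < 4L) cuts[ci + 1L] - eps else Inf)
      if (lo > hi) next
      cand <- unique(c(qs[qs >= lo & qs <= hi], lo, hi, cuts[ci]))
      cand <- sort(cand)
      for (cc in cand) {
        if (n_eval >= spec$max_evaluations) break
        trial <- cuts[2:4]
        trial[i] <- cc
        a <- obj(trial)
        if (a > best + spec$tolerance ||
            (a >= best && cc < cuts[ci])) {
          if (a >= best) {
            if (a > best) improved <- TRUE
            best <- a
            cuts[ci] <- cc
          }
        }
      }
      # local polish: data-midpoint refinement around the current cut
      nb <- sort(v[v >= lo & v <= hi])
      if (length(nb) > 1L) {
        mid <- (nb[-1] + nb[-length(nb)]) / 2
        near <- mid[order(abs(mid - cuts[ci]))][seq_len(min(25L, length(mid)))]
        for (cc in sort(near)) {
          if (n_eval >= spec$max_evaluations) break
          trial <- cuts[2:4]
          trial[i] <- cc
          a <- obj(trial)
          if (a > best + spec$tolerance || (a >= best && cc < cuts[ci])) {
            if (a >= best) {
              if (a > best) improved <- TRUE
              best <- a
              cuts[ci] <- cc
            }
          }
        }
      }
    }
    if (!improved || n_eval >= spec$max_evaluations) break
  }
  cuts[1] <- min(max(cuts[1], bounds[1, 1]), cuts[2] - eps)
  if (cuts[1] <= 0) cuts[1] <- cuts[2] / 2
  list(
    thresholds = threshold_set(epochs$measure, epochs$sample_rate_hz,
                               cuts[1], cuts[2], cuts[3], cuts[4]),
    accuracy = best, init_accuracy = init_acc, n_evaluations = n_eval
  )
}

#' Leave-one-participant-out evaluation of one measure
#'
#' For each of the N participants, thresholds are optimized on the pooled
#' epochs of the other N-1 and evaluated on the held-out participant.
#'
#' @param cohort List of participants, each a list with `epochs` (an
#'   [epoch_series()]) and `labels` (a [label_series()]).
#' @param spec An [optimizer_spec()].
#' @return List with `folds` (per-fold `thresholds`, `confusion`,
#'   `accuracy`), `pooled` (summed `pa_confusion`), `pooled_accuracy`, and
#'   `mean_accuracy` (unweighted mean of per-participant accuracies).
#' @export
lopo_run <- function(cohort, spec = optimizer_spec()) {
  N <- length(cohort)
  if (N < 2L) {
    stop_wristpa("leave-one-participant-out needs >= 2 participants",
                 "config_error")
  }
  pool_epochs <- function(parts) {
    off <- 0
    es <- lapply(parts, function(p) {
      e <- p$epochs
      e$epoch_start <- e$epoch_start + off
      off <<- max(e$epoch_start) + 60
      e
    })
    epoch_series(unlist(lapply(es, `[[`, "epoch_start")),
                 unlist(lapply(es, `[[`, "values")),
                 parts[[1]]$epochs$measure,
                 parts[[1]]$epochs$sample_rate_hz)
  }
  pool_labels <- function(parts) {
    off <- 0
    ls <- lapply(parts, function(p) {
      l <- p$labels
      l$epoch_start <- l$epoch_start + off
      off <<- max(l$epoch_start) + 60
      l
    })
    label_series(unlist(lapply(ls, `[[`, "epoch_start")),
                 unlist(lapply(ls, function(l) as.character(l$category))))
  }
  folds <- lapply(seq_len(N), function(i) {
    train <- cohort[-i]
    fit <- optimize_thresholds(pool_epochs(train), pool_labels(train), spec)
    est <- suppressWarnings(
      classify_epochs(cohort[[i]]$epochs, fit$thresholds))
    cm <- confusion(cohort[[i]]$labels, est)
    list(thresholds = fit$thresholds, confusion = cm, accuracy = accuracy(cm),
         train_accuracy = fit$accuracy)
  })
  pooled <- Reduce(`+`, lapply(folds, `[[`, "confusion"))
  list(folds = folds, pooled = pooled, pooled_accuracy = accuracy(pooled),
       mean_accuracy = mean(vapply(folds, `[[`, numeric(1), "accuracy")))
}
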