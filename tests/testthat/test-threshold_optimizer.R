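test_that("diffusion KDE normalizes and locates the mode", {
  set.seed(10)
  s <- rnorm(10000)
  k <- kde_diffusion(s)
  dx <- diff(k$x[1:2])
  expect_lt(abs(sum(k$density) * dx - 1), 1e-3)
  expect_true(all(k$density >= 0))
  expect_lt(abs(k$x[which.max(k$density)]), 0.1)
  expect_error(kde_diffusion(rep(1, 100)), class = "wristpa_data_error")
  expect_error(kde_diffusion(rnorm(10)), class = "wristpa_data_error")
})

test_that("diffusion KDE separates a bimodal mixture", {
  set.seed(11)
  s <- c(rnorm(4000, 0), rnorm(4000, 6))
  k <- kde_diffusion(s)
  mid <- k$density[k$x > 2 & k$x < 4]
  peak <- max(k$density)
  expect_lt(max(mid), 0.5 * peak)  # a genuine valley between the modes
})

test_that("density-valley initialization lands between class modes", {
  set.seed(12)
  strat <- list(sedentary = rnorm(2000, 0), light = rnorm(2000, 10))
  th <- suppressWarnings(init_thresholds(strat, "rocam", 10))
  expect_lt(abs(th$sed_light - 5), 0.5)

  strat3 <- list(sedentary = rnorm(2000, 0, 1), light = rnorm(2000, 5, 1),
                 moderate = rnorm(2000, 10, 1))
  th3 <- suppressWarnings(init_thresholds(strat3, "rocam", 10))
  expect_lt(abs(th3$sed_light - 2.5), 0.5)
  expect_lt(abs(th3$light_mod - 7.5), 0.5)
  expect_lt(th3$sed_light, th3$light_mod)

  # identical adjacent distributions fall back to the bound midpoint
  same <- list(sedentary = rnorm(2000, 5), light = rnorm(2000, 5))
  w <- capture_warnings(init_thresholds(same, "rocam", 10))
  expect_true(any(grepl("sedentary/light.*bound midpoint", w)))
})

test_that("optimizer recovers Bayes boundaries of Gaussian classes", {
  gd <- gaussian_epochs(5000, means = c(2, 4, 6, 8), sds = rep(0.5, 4),
                        seed = 13)
  fit <- suppressWarnings(optimize_thresholds(gd$epochs, gd$labels))
  cuts <- c(fit$thresholds$sed_light, fit$thresholds$light_mod,
            fit$thresholds$mod_vig)
  bayes <- c(3, 5, 7)  # midpoints of adjacent equal-variance means
  expect_true(all(abs(cuts - bayes) / bayes < 0.05))
  expect_gte(fit$accuracy, fit$init_accuracy)
  expect_true(fit$thresholds$sleep_floor < fit$thresholds$sed_light)
})

test_that("optimizer is a fixed point on separable data and rejects degenerate labels", {
  gd <- gaussian_epochs(500, means = c(2, 8), sds = c(0.1, 0.1), seed = 14)
  init <- threshold_set("rocam", 10, 0.5, 5, 8.8, 9.0)
  fit <- suppressWarnings(optimize_thresholds(
    gd$epochs, gd$labels,
    optimizer_spec(bounds = cbind(c(0.1, 4, 8.5, 8.9), c(1, 6, 8.9, 9.5)),
                   init = init)))
  expect_equal(fit$accuracy, 1.0)
  expect_equal(fit$thresholds$sed_light, 5, tolerance = 0.5)

  t <- (0:99) * 60
  one <- label_series(t, rep("light", 100))
  ep <- epoch_series(t, runif(100), "rocam", 10)
  expect_error(optimize_thresholds(ep, one), class = "wristpa_data_error")
})

test_that("returned threshold sets always satisfy ordering and bounds", {
  for (seed in 1:3) {
    gd <- gaussian_epochs(300, means = c(1, 2, 3, 4), sds = rep(0.6, 4),
                          seed = seed)
    fit <- suppressWarnings(optimize_thresholds(gd$epochs, gd$labels))
    th <- fit$thresholds
    cuts <- c(th$sleep_floor, th$sed_light, th$light_mod, th$mod_vig)
    expect_true(all(diff(cuts) > 0))
    expect_gt(cuts[1], 0)
  }
})

test_that("LOPO tests each participant exactly once and conserves minutes", {
  parts <- lapply(1:3, function(i) {
    gd <- gaussian_epochs(80, means = c(1, 2, 3, 4), sds = rep(0.3, 4),
                          seed = 20 + i)
    list(epochs = gd$epochs, labels = gd$labels)
  })
  res <- suppressWarnings(lopo_run(parts))
  expect_length(res$folds, 3L)
  total <- sum(vapply(res$folds, function(f) sum(f$confusion), numeric(1)))
  expect_equal(total, 3 * 4 * 80)
  expect_equal(sum(res$pooled), total)
  expect_error(lopo_run(parts[1]), class = "wristpa_config_error")
})

test_that("identical participants give near-identical fold thresholds", {
  gd <- gaussian_epochs(150, means = c(1, 3, 5, 7), sds = rep(0.4, 4),
                        seed = 30)
  parts <- list(list(epochs = gd$epochs, labels = gd$labels),
                list(epochs = gd$epochs, labels = gd$labels),
                list(epochs = gd$epochs, labels = gd$labels))
  res <- suppressWarnings(lopo_run(parts))
  cuts <- vapply(res$folds, function(f) {
    c(f$thresholds$sed_light, f$thresholds$light_mod, f$thresholds$mod_vig)
  }, numeric(3))
  expect_lt(max(apply(cuts, 1, function(r) diff(range(r)))), 1e-9)
})
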