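test_that("ENMONZ matches its closed form on hand-picked vectors", {
  rec <- make_record(c(0, 0.6, 2, 0), c(0, 0.8, 2, 0), c(1, 0, 1, 0.2))
  expect_equal(enmonz(rec)$values, c(0, 0, 2, 0))
})

test_that("MAD equals the mean absolute deviation of the vector norm", {
  # EN values 1.2, 0.8, 1.2, 0.8: mean 1.0, mean absolute deviation 0.2
  rec <- make_record(c(1.2, 0.8, 1.2, 0.8), rep(0, 4), rep(0, 4), rate = 4)
  v <- mad_measure(rec, measure_config(mad_window_seconds = 1))
  expect_equal(v$values, 0.2)

  # EN values 1, 1, 1, 2: mean 1.25; deviations 0.25, 0.25, 0.25, 0.75
  rec <- make_record(c(1, 1, 1, 2), rep(0, 4), rep(0, 4), rate = 4)
  v <- mad_measure(rec, measure_config(mad_window_seconds = 1))
  expect_equal(v$values, 0.375)

  expect_equal(mad_measure(constant_record(1200))$values, rep(0, 2))
  expect_error(mad_measure(constant_record(10),
                           measure_config(mad_window_seconds = 60)),
               class = "wristpa_data_error")
})

test_that("Activity Index uses population variances averaged over axes", {
  rec <- make_record(rep(c(1, -1), 10), rep(0, 20), rep(0, 20), rate = 10)
  expect_equal(activity_index(rec)$values, rep(1 / 3, 2))
  expect_equal(activity_index(constant_record())$values, rep(0, 4))
  # noise variance larger than the signal variance clamps to zero
  v <- activity_index(rec, measure_config(ai_noise_variance = 2))
  expect_equal(v$values, rep(0, 2))
})

test_that("ROCAM is the filtered norm of successive differences", {
  expect_equal(rocam(constant_record(100))$values, rep(0, 100))

  # linear ramp: every difference is the slope, the median keeps it
  n <- 100
  rec <- make_record(0.01 * (0:(n - 1)), rep(0, n), rep(1, n))
  v <- rocam(rec)$values
  expect_equal(v[5:(n - 5)], rep(0.01, n - 9), tolerance = 1e-12)

  # a single one-sample spike vanishes under the 1-second median
  x <- rep(0, 100); x[50] <- 1
  rec <- make_record(x, rep(0, 100), rep(1, 100))
  v <- rocam(rec)$values
  expect_equal(v[50], 0)
})

test_that("epoch aggregation averages measures and sums AI", {
  rec <- constant_record(1200, rate = 10)  # 2 minutes
  ms <- rocam(rec)
  ms$values <- rep(0.2, length(ms$values))
  ep <- epoch_aggregate(ms)
  expect_equal(ep$values, c(0.2, 0.2))

  ai <- activity_index(rec)
  ai$values <- rep(1 / 3, length(ai$values))
  ep <- epoch_aggregate(ai)
  expect_equal(ep$values, rep(20, 2))

  # 90 s of data: second minute is partial and flagged unknown
  rec <- constant_record(900, rate = 10)
  ep <- epoch_aggregate(enmonz(rec))
  expect_equal(length(ep$values), 1L)
})

test_that("vectorized measures match naive loop oracles on random data", {
  rec <- random_record(2000, rate = 10, seed = 42)
  cfg <- measure_config(mad_window_seconds = 6)
  expect_equal(enmonz(rec)$values,
               naive_enmonz(rec$x, rec$y, rec$z), tolerance = 1e-12)
  expect_equal(mad_measure(rec, cfg)$values,
               naive_mad(rec$x, rec$y, rec$z, 60), tolerance = 1e-12)
  expect_equal(activity_index(rec)$values,
               naive_ai(rec$x, rec$y, rec$z, 10), tolerance = 1e-12)
  expect_equal(rocam(rec)$values,
               naive_rocam(rec$x, rec$y, rec$z, 10), tolerance = 1e-12)
})

test_that("all measures are non-negative and ENMONZ is bounded by the norm", {
  rec <- random_record(3000, seed = 7, scale = 1)
  en <- sqrt(rec$x^2 + rec$y^2 + rec$z^2)
  for (v in list(enmonz(rec)$values, mad_measure(rec)$values,
                 activity_index(rec)$values, rocam(rec)$values)) {
    expect_true(all(v >= 0))
  }
  expect_true(all(enmonz(rec)$values <= en))
  low <- en <= 1
  expect_true(all(enmonz(rec)$values[low] == 0))
})

test_that("per-epoch ROCAM grows as the sample rate drops", {
  # fixed band-limited signal: tones well inside the 10 Hz passband
  t <- (0:(100 * 600 - 1)) / 100
  rec <- make_record(0.3 * sin(2 * pi * 2 * t) + 0.2 * sin(2 * pi * 3.5 * t),
                     0.25 * sin(2 * pi * 2.6 * t), 1 + 0.2 * sin(2 * pi * 1.4 * t),
                     rate = 100)
  rates <- c(100, 50, 25, 10)
  m <- vapply(rates, function(r) {
    rr <- if (r == 100) rec else downsample(rec, r)
    mean(epoch_aggregate(rocam(rr))$values, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(m) > 0))  # increasing as rate decreases
})
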