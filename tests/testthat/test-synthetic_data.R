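zero_motion_params <- function() {
  mp <- default_motion_params()
  mp$amp_g <- c(0, 1e-6, 2e-6, 3e-6, 4e-6)  # keep strict ordering
  mp$noise_sd_g[] <- 0
  mp$reorient_rate[] <- 0
  mp
}

test_that("gravity-only limit gives a constant unit-norm stream", {
  prof <- synthetic_profile(
    schedule = data.frame(category = "sleep", minutes = 2),
    motion_params = zero_motion_params(), sample_rate_hz = 100, seed = 5)
  day <- generate_day(prof)
  rec <- day$record
  expect_lt(max(abs(diff(rec$x)), abs(diff(rec$y)), abs(diff(rec$z))), 1e-9)
  norm1 <- sqrt(rec$x^2 + rec$y^2 + rec$z^2)
  expect_equal(norm1, rep(1, length(norm1)), tolerance = 1e-9)
  expect_true(all(day$labels$category == "sleep"))
})

test_that("generation is bit-reproducible under a fixed seed", {
  prof <- synthetic_profile(
    schedule = data.frame(category = c("sleep", "light"), minutes = c(2, 2)),
    sample_rate_hz = 10, seed = 99)
  a <- generate_day(prof)
  b <- generate_day(prof)
  expect_identical(a$record$x, b$record$x)
  expect_identical(a$record$z, b$record$z)
  expect_identical(as.character(a$labels$category),
                   as.character(b$labels$category))
})

test_that("default vigorous minutes exceed the vigorous ROCAM cut", {
  prof <- synthetic_profile(
    schedule = data.frame(category = "vigorous", minutes = 5),
    sample_rate_hz = 10, seed = 21)
  day <- generate_day(prof)
  ep <- epoch_aggregate(rocam(day$record))
  expect_gt(mean(ep$values, na.rm = TRUE), 0.483)
})

test_that("per-category mean ROCAM keeps the intensity ordering", {
  prof <- synthetic_profile(schedule = short_schedule(),
                            sample_rate_hz = 10, seed = 31)
  day <- generate_day(prof)
  ep <- epoch_aggregate(rocam(day$record))
  cats <- c("sleep", "sedentary", "light", "moderate", "vigorous")
  m <- vapply(cats, function(cc) {
    mean(ep$values[as.character(day$labels$category) == cc], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(m) > 0))
  # labels and record cover the same span
  expect_equal(length(day$labels$epoch_start) * 60,
               round(diff(range(day$record$time)) + 1 / 10))
})

test_that("cohorts are reproducible, distinct, and match the schedule mix", {
  prof <- synthetic_profile(
    schedule = data.frame(category = c("sleep", "sedentary", "light"),
                          minutes = c(5, 5, 5)),
    sample_rate_hz = 10, seed = 1)
  coh <- generate_cohort(3, prof, seed = 8)
  coh2 <- generate_cohort(3, prof, seed = 8)
  expect_length(coh, 3L)
  expect_identical(coh[[2]]$record$x, coh2[[2]]$record$x)
  expect_false(identical(coh[[1]]$record$x, coh[[2]]$record$x))
  expect_error(generate_cohort(1, prof), class = "wristpa_config_error")

  coh5 <- generate_cohort(5, prof, seed = 4)
  pooled <- unlist(lapply(coh5, function(d) as.character(d$labels$category)))
  props <- table(pooled) / length(pooled)
  expect_true(all(abs(props - 1 / 3) < 0.05))
})

test_that("non-wear injection freezes the window and the detector finds it", {
  sch <- data.frame(category = c("sedentary", "light", "sedentary"),
                    minutes = c(30, 80, 30))
  prof <- synthetic_profile(schedule = sch, sample_rate_hz = 10, seed = 13)
  day <- generate_day(prof)

  inj0 <- inject_nonwear(day$record, day$labels, 35, 70, noise_sd = 0,
                         seed = 2)
  idx <- inj0$record$time >= 35 * 60 & inj0$record$time < 105 * 60
  expect_equal(sd(inj0$record$x[idx]), 0)
  expect_equal(sum(inj0$labels$category == "nonwear"), 70L)

  inj <- inject_nonwear(day$record, day$labels, 35, 70, seed = 2)
  mask <- detect_nonwear(inj$record)
  flagged <- which(mask)
  expect_gte(min(flagged), 35)   # 0-based minute 35 -> index 36, +/- 1
  expect_lte(max(flagged), 106)
  expect_gte(length(flagged), 68)

  expect_error(inject_nonwear(day$record, day$labels, 35, 0),
               class = "wristpa_range_error")
  expect_error(inject_nonwear(day$record, day$labels, 130, 30),
               class = "wristpa_range_error")
})

test_that("degenerate profiles are rejected", {
  expect_error(synthetic_profile(schedule = data.frame()),
               class = "wristpa_config_error")
  expect_error(
    synthetic_profile(schedule = data.frame(category = "jogging", minutes = 5)),
    class = "wristpa_config_error")
})
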