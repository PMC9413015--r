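test_that("confusion counts, accuracy, and per-category rates", {
  t <- (0:99) * 60
  truth <- label_series(t, rep(c("sleep", "light"), 50))
  expect_equal(accuracy(confusion(truth, truth)), 1.0)

  t3 <- (0:2) * 60
  tr <- label_series(t3, c("sleep", "light", "light"))
  es <- label_series(t3, c("sleep", "light", "moderate"))
  cm <- confusion(tr, es)
  expect_equal(accuracy(cm), 2 / 3)
  expect_equal(unname(per_category_rate(cm)["light"]), 0.5)

  other <- label_series(t3 + 60, c("sleep", "light", "light"))
  expect_error(confusion(tr, other), class = "wristpa_alignment_error")
})

test_that("non-wear and unknown minutes are excluded and matrices add", {
  t <- (0:5) * 60
  tr <- label_series(t, c("sleep", "light", "nonwear", "moderate", "light",
                          "unknown"))
  es <- label_series(t, c("sleep", "light", "light", "moderate", "unknown",
                          "light"))
  cm <- confusion(tr, es)
  expect_equal(sum(cm), 3)

  tr_a <- label_series(t[1:3], as.character(tr$category)[1:3])
  es_a <- label_series(t[1:3], as.character(es$category)[1:3])
  tr_b <- label_series(t[4:6], as.character(tr$category)[4:6])
  es_b <- label_series(t[4:6], as.character(es$category)[4:6])
  expect_equal(unclass(confusion(tr_a, es_a) + confusion(tr_b, es_b)),
               unclass(cm))
})

test_that("Spearman association handles monotone and tied data", {
  t <- (0:4) * 60
  lab <- label_series(t, c("sleep", "sedentary", "light", "moderate",
                           "vigorous"))
  v_up <- pa_code(lab) * 0.1 + 0.01
  expect_equal(as.numeric(spearman_assoc(epoch_series(t, v_up, "rocam"), lab)),
               1.0)
  v_dn <- 1 - pa_code(lab) * 0.1
  expect_equal(as.numeric(spearman_assoc(epoch_series(t, v_dn, "rocam"), lab)),
               -1.0)

  # ties: compare against an explicit rank-then-product-moment oracle
  t6 <- (0:5) * 60
  lab6 <- label_series(t6, c("sleep", "sleep", "light", "light", "moderate",
                             "vigorous"))
  v6 <- c(0.1, 0.2, 0.2, 0.5, 0.5, 0.9)
  got <- as.numeric(spearman_assoc(epoch_series(t6, v6, "rocam"), lab6))
  expect_equal(got, spearman_oracle(v6, pa_code(lab6)), tolerance = 1e-12)

  const <- epoch_series(t6, rep(0.3, 6), "rocam")
  expect_error(spearman_assoc(const, lab6),
               class = "wristpa_undefined_correlation")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(4)
  t <- (0:199) * 60
  lab <- label_series(t, sample(c("sedentary", "light", "moderate"), 200,
                                replace = TRUE))
  v <- pa_code(lab) + rnorm(200)
  v <- v - min(v) + 0.01
  r1 <- as.numeric(spearman_assoc(epoch_series(t, v, "rocam"), lab))
  r2 <- as.numeric(spearman_assoc(epoch_series(t, sqrt(v), "rocam"), lab))
  r3 <- as.numeric(spearman_assoc(epoch_series(t, v^3, "rocam"), lab))
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(r1, r3, tolerance = 1e-12)
})

test_that("KS statistic matches exhaustive ECDF scanning", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)

  a <- c(1, 2, 3)
  b <- c(1.5, 2.5)
  expect_equal(ks_two_sample(a, b)$statistic, ks_oracle(a, b))

  set.seed(6)
  for (i in 1:5) {
    a <- rnorm(20 + i)
    b <- rnorm(15 + i, 0.5)
    expect_equal(ks_two_sample(a, b)$statistic, ks_oracle(a, b))
    # invariance under a common strictly monotone transform
    expect_equal(ks_two_sample(exp(a), exp(b))$statistic,
                 ks_two_sample(a, b)$statistic)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), class = "wristpa_data_error")
})

test_that("significance is decided at the 0.01 level", {
  set.seed(8)
  same <- ks_two_sample(rnorm(200), rnorm(200))
  expect_false(same$significant)
  diff_ <- ks_two_sample(rnorm(200), rnorm(200, 3))
  expect_true(diff_$significant)
  expect_lt(diff_$p_value, 1e-4)
})

test_that("per-participant and pooled accuracies are both reported", {
  m1 <- structure(matrix(c(8, 2, 0, 10), 2,
                         dimnames = list(c("sleep", "light"),
                                         c("sleep", "light"))),
                  class = "pa_confusion")
  m2 <- structure(matrix(c(50, 0, 0, 50), 2,
                         dimnames = list(c("sleep", "light"),
                                         c("sleep", "light"))),
                  class = "pa_confusion")
  s <- per_participant_summary(list(m1, m2))
  expect_equal(unname(s$per_participant), c(0.9, 1.0))
  expect_equal(s$mean_accuracy, 0.95)
  expect_equal(s$pooled_accuracy, 118 / 120)  # unequal minutes: differs
  s1 <- per_participant_summary(list(m1))
  expect_equal(s1$mean_accuracy, s1$pooled_accuracy)
})
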