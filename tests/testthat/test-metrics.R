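test_that("extrema_in_window finds analytic sinusoid extrema", {
  rate <- 120
  t <- (0:119) / rate
  e <- extrema_in_window(-sin(2 * pi * t), rate, c(0, 1), t0 = 0)
  expect_equal(e$min_z, -1, tolerance = 1e-3)
  expect_equal(e$neg_latency, 0.25, tolerance = 1 / rate)
  expect_equal(e$max_z, 1, tolerance = 1e-3)
  expect_equal(e$pos_latency, 0.75, tolerance = 1 / rate)
})

test_that("extrema ties break to the first occurrence", {
  rate <- 10
  x <- rep(0, 10)
  x[c(3, 7)] <- -2          # duplicate minima at t = 0.2 and 0.6
  e <- extrema_in_window(x, rate, c(0, 1), t0 = 0)
  expect_equal(e$neg_latency, 0.2)
  const <- extrema_in_window(rep(4, 20), rate, c(0, 2), t0 = 0)
  expect_equal(const$min_z, 4)
  expect_equal(const$max_z, 4)
  expect_equal(const$neg_latency, 0)
  expect_equal(const$pos_latency, 0)
  expect_error(extrema_in_window(x, rate, c(1, 1)), "a < b")
})

test_that("extrema agree with an exhaustive scan on random inputs", {
  set.seed(77)
  rate <- 60
  for (rep in 1:25) {
    x <- rnorm(300)
    a <- sample(0:2, 1); b <- a + sample(1:2, 1)
    e <- extrema_in_window(x, rate, c(a, b), t0 = 0)
    idx <- which((seq_along(x) - 1) / rate >= a &
                   (seq_along(x) - 1) / rate < b)
    best_min <- idx[1]; best_max <- idx[1]
    for (i in idx) {
      if (x[i] < x[best_min]) best_min <- i
      if (x[i] > x[best_max]) best_max <- i
    }
    expect_identical(e$min_z, x[best_min])
    expect_identical(e$max_z, x[best_max])
    expect_equal(e$neg_latency, (best_min - idx[1]) / rate)
    expect_equal(e$pos_latency, (best_max - idx[1]) / rate)
  }
})

test_that("burst_metrics uses onset z as the per-burst baseline", {
  rate <- 120
  zero <- numeric(15 * rate)
  rel <- (seq_along(zero) - 1) / rate - 5
  bm0 <- burst_metrics(zero, 0:9, window = 1, rate = rate, rel_time = rel)
  expect_equal(bm0$neg_amplitude, numeric(10))
  expect_equal(bm0$pos_amplitude, numeric(10))
  # synthetic dip of known depth measured from a nonzero onset value
  trace <- rep(0.5, 8 * rate)
  rel2 <- (seq_along(trace) - 1) / rate - 5
  dip_idx <- which(rel2 >= 0.4 & rel2 < 0.6)
  trace[dip_idx] <- 0.5 - 1.5
  bm <- burst_metrics(trace, 0, window = 1, rate = rate, rel_time = rel2)
  expect_equal(bm$onset_z, 0.5)
  expect_equal(bm$neg_amplitude, 1.5)
  expect_equal(bm$neg_latency, 0.4, tolerance = 1 / rate)
  expect_true(all(bm$neg_amplitude >= 0 & bm$pos_amplitude >= 0))
})

test_that("amplitudes are non-negative on random traces", {
  set.seed(83)
  rate <- 120
  for (rep in 1:10) {
    trace <- rnorm(15 * rate)
    rel <- (seq_along(trace) - 1) / rate - 5
    bm <- burst_metrics(trace, 0:9, window = 1, rate = rate, rel_time = rel)
    expect_true(all(bm$neg_amplitude >= 0))
    expect_true(all(bm$pos_amplitude >= 0))
    expect_true(all(bm$min_z <= bm$max_z))
  }
})

test_that("peak_ratio follows the signed-amplitude convention", {
  expect_equal(peak_ratio(-1.07, -1.00), 1.07)
  expect_equal(peak_ratio(2.2, 2.2), 1.0)
  expect_true(is.na(peak_ratio(0.5, 1e-9, eps = 1e-6)))
})

test_that("classification threshold is strict at 2.58", {
  expect_equal(classify_subject(c(1.2, 2.0, 3.74)), "increase")
  expect_equal(classify_subject(2.58), "decrease")
  expect_equal(classify_subject(rep(1.5, 4)), "decrease")
  expect_error(classify_subject(numeric(0)), "non-empty")
})

test_that("raising the threshold only converts increase to decrease", {
  set.seed(89)
  for (rep in 1:50) {
    mx <- runif(4, 0, 5)
    th <- sort(runif(2, 0, 5))
    lo <- classify_subject(mx, th[1])
    hi <- classify_subject(mx, th[2])
    expect_false(lo == "decrease" && hi == "increase")
  }
})

test_that("summarize_subject recovers the noiseless generator summaries", {
  sch <- make_schedule(rep(c(45, 65, 85, 105), each = 2), seed = 13)
  kern <- kernel_params(dip_slope = -0.020, rebound_amplitude = 0,
                        onset_transient_amplitude = 0)
  aligned <- noiseless_aligned(kern, sch)
  ss <- summarize_subject(aligned, sch, "s1")
  expect_s3_class(ss, "subject_summary")
  expect_equal(ss$phenotype, "decrease")
  # avg_min decreases monotonically with intensity and hits the closed form
  expect_true(all(diff(ss$table$avg_min) < 0))
  expect_equal(ss$table$avg_min[4], -0.020 * 60, tolerance = 5e-3)
  expect_equal(ss$table$avg_min[1], 0, tolerance = 1e-6)
  # increase-type subject: first_max at 85 dB equals the configured transient
  kern_inc <- kernel_params(onset_transient_amplitude = 3.59,
                            rebound_amplitude = 0, dip_slope = 0)
  al_inc <- noiseless_aligned(kern_inc, sch, phenotype = "increase")
  ss_inc <- summarize_subject(al_inc, sch, "s2")
  expect_equal(ss_inc$phenotype, "increase")
  expect_equal(ss_inc$table$first_max[ss_inc$table$intensity == 85],
               3.59, tolerance = 0.02)
})

test_that("all-zero traces summarise to zeros and decrease", {
  sch <- make_schedule(c(45, 105), seed = 1)
  kern0 <- kernel_params(dip_slope = 0, rebound_amplitude = 0,
                         onset_transient_amplitude = 0)
  aligned <- noiseless_aligned(kern0, sch)
  ss <- summarize_subject(aligned, sch)
  expect_equal(ss$phenotype, "decrease")
  expect_true(all(abs(as.matrix(
    ss$table[, c("first_min", "first_max", "avg_min", "avg_max")])) < 1e-12))
})

test_that("build_long_table reshapes summaries for the trend fit", {
  sch <- make_schedule(rep(c(45, 105), each = 2), seed = 4)
  kern <- kernel_params(rebound_amplitude = 0,
                        onset_transient_amplitude = 0)
  s1 <- summarize_subject(noiseless_aligned(kern, sch), sch, "a")
  s2 <- summarize_subject(noiseless_aligned(kern, sch), sch, "b")
  lt <- build_long_table(list(s1, s2), "min", "average")
  expect_equal(nrow(lt), 4L)
  expect_setequal(lt$subject_id, c("a", "b"))
  expect_equal(lt$value[lt$subject_id == "a"], s1$table$avg_min)
  expect_error(build_long_table(list(s1), "min", "average",
                                phenotype = "increase"), "no subjects")
})
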