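test_that("null kernel and zero noise give the pure drift baseline", {
  sch <- make_schedule(c(85, 85), seed = 2)
  k0 <- kernel_params(dip_slope = 0, rebound_amplitude = 0,
                      onset_transient_amplitude = 0)
  subj <- subject_params("s1", "decrease", noise_sd = 0,
                         drift_amplitude = 0.2, drift_period = 120)
  tr <- simulate_subject(subj, k0, sch, rate = 120, seed = 4)
  t <- tr$t0 + (seq_along(tr$values) - 1) / tr$rate
  expect_equal(tr$values, 0.2 * sin(2 * pi * t / 120), tolerance = 1e-12)
})

test_that("noiseless trace matches the independent continuous-time model", {
  sch <- make_schedule(c(65, 105), seed = 9)
  kern <- kernel_params()
  subj <- subject_params("s1", "increase", noise_sd = 0, drift_amplitude = 0)
  tr <- simulate_subject(subj, kern, sch, rate = 120, seed = 1)
  t <- (seq_along(tr$values) - 1) / tr$rate
  expect_equal(tr$values,
               oracle_response(t, kern, sch, phenotype = "increase"),
               tolerance = 1e-10)
})

test_that("decrease-type dip recovers the closed-form kernel minimum", {
  # single 105-dB trial, no rebound, no drift: the across-burst averaged
  # segment bottoms out at dip_slope * (105 - 45) because the dip kernel is
  # peak-normalised to 1 (grid discretisation and tail overlap < 0.5%).
  sch <- make_schedule(105, seed = 5)
  kern <- kernel_params(dip_slope = -0.020, rebound_amplitude = 0,
                        onset_transient_amplitude = 0)
  aligned <- noiseless_aligned(kern, sch)
  avg <- average_trials(aligned)
  segs <- segment_bursts(avg[1, ], burst_onsets(sch), window = 1,
                         rate = aligned$rate,
                         rel_time = aligned$rel_time)
  expect_equal(min(colMeans(segs)), -0.020 * 60, tolerance = 5e-3)
  # the dip minimum lands at dip_latency + rise/2 + analytic kernel peak time
  tpk <- with(kern, dip_rise_tau * dip_decay_tau /
                (dip_decay_tau - dip_rise_tau) *
                log(dip_decay_tau / dip_rise_tau))
  lat <- (which.min(colMeans(segs)) - 1) / aligned$rate
  expect_equal(lat, kern$dip_latency + sch$rise_time / 2 + tpk,
               tolerance = 2 / aligned$rate)
})

test_that("increase-type onset transient appears on burst 1 only", {
  sch <- make_schedule(c(85, 85, 85), seed = 6)
  kern <- kernel_params(onset_transient_amplitude = 3.6,
                        habituation_factor = 0, rebound_amplitude = 0,
                        dip_slope = 0)
  aligned <- noiseless_aligned(kern, sch, phenotype = "increase")
  avg <- average_trials(aligned)
  bm <- burst_metrics(avg[1, ], burst_onsets(sch), window = 1,
                      rate = aligned$rate, rel_time = aligned$rel_time)
  expect_equal(bm$pos_amplitude[1], 3.6, tolerance = 0.01)
  expect_lt(max(bm$pos_amplitude[-1]), 0.01)
  # P2/P1 ~ 0, mirroring the vanishing second transient
  expect_equal(peak_ratio(bm$max_z[2] - bm$onset_z[2],
                          bm$max_z[1] - bm$onset_z[1]),
               0, tolerance = 0.01)
})

test_that("habituation_factor scales later-burst transients geometrically", {
  sch <- make_schedule(85, seed = 6)
  kern <- kernel_params(onset_transient_amplitude = 2,
                        habituation_factor = 0.5, rebound_amplitude = 0,
                        dip_slope = 0)
  aligned <- noiseless_aligned(kern, sch, phenotype = "increase")
  avg <- average_trials(aligned)
  bm <- burst_metrics(avg[1, ], burst_onsets(sch), window = 1,
                      rate = aligned$rate, rel_time = aligned$rel_time)
  expect_equal(bm$pos_amplitude[1:4], 2 * 0.5^(0:3), tolerance = 0.02)
})

test_that("simulate_cohort is reproducible and honours p_increase", {
  sch <- make_schedule(c(45, 105), seed = 1)
  cfg <- cohort_config(n_subjects = 9, p_increase = 0, seed = 21)
  co <- simulate_cohort(cfg, sch)
  expect_length(co$traces, 9L)
  expect_true(all(vapply(co$subjects, `[[`, "", "phenotype") == "decrease"))
  co2 <- simulate_cohort(cfg, sch)
  expect_identical(co, co2)
  cfg3 <- cohort_config(n_subjects = 9, p_increase = 0, seed = 22)
  co3 <- simulate_cohort(cfg3, sch)
  expect_false(identical(co$traces[[1]]$values, co3$traces[[1]]$values))
  cfg_inc <- cohort_config(n_subjects = 5, p_increase = 1, seed = 21)
  co_inc <- simulate_cohort(cfg_inc, sch)
  expect_true(all(vapply(co_inc$subjects, `[[`, "", "phenotype") == "increase"))
})

test_that("no heterogeneity and no noise give identical subjects", {
  sch <- make_schedule(c(85, 105), seed = 2)
  cfg <- cohort_config(n_subjects = 3, between_subject_slope_sd = 0,
                       noise_sd = 0, drift_amplitude = 0, seed = 8)
  co <- simulate_cohort(cfg, sch)
  expect_equal(co$traces[[1]]$values, co$traces[[2]]$values)
  expect_equal(co$traces[[2]]$values, co$traces[[3]]$values)
})

test_that("per-subject fitted slopes reflect the between-subject variance", {
  # clustering property: var of per-subject slopes ~ slope_sd^2 + sampling
  # variance; checked over 200 noiseless-measurement cohorts by reusing the
  # generator's ground-truth draws
  sd_true <- 0.004
  devs <- vapply(1:200, function(s) {
    cfg <- cohort_config(n_subjects = 2, between_subject_slope_sd = sd_true,
                         seed = s)
    sch <- make_schedule(c(45, 105), seed = 1)
    co <- simulate_cohort(cfg, sch)
    co$subjects[[1]]$slope_deviation
  }, 0)
  expect_equal(sd(devs), sd_true, tolerance = 0.15)
})

test_that("ramped responses peak later than damped ones (noiseless)", {
  kern <- kernel_params()
  lat <- vapply(c(ramped = "ramped", damped = "damped"), function(e) {
    sch <- make_schedule(rep(85, 3), envelope = e, seed = 3)
    aligned <- noiseless_aligned(kern, sch)
    avg <- average_trials(aligned)
    segs <- segment_bursts(avg[1, ], burst_onsets(sch), window = 1,
                           rate = aligned$rate, rel_time = aligned$rel_time)
    m <- colMeans(segs)
    (which.min(m) - 1) / aligned$rate
  }, 0)
  expect_gt(lat[["ramped"]], lat[["damped"]])
})

test_that("simulate_pupil calibrates the 105-dB mean z to 0.33", {
  tr <- simulate_pupil(c(20, 60), c(45, 105), noise_sd = 0)
  expect_equal(tr$rate, 30)
  resp <- pupil_response(tr, c(20, 60), normalize = FALSE)
  expect_equal(resp[2], 0.33, tolerance = 1e-6)
  expect_equal(resp[1], 0, tolerance = 1e-9)   # 45 dB is the anchor level
  expect_lt(resp[1], resp[2])                  # monotone in intensity
  flat <- simulate_pupil(c(20), c(105), gain = 0, noise_sd = 0)
  expect_equal(flat$values, rep(100, length(flat$values)))
})
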