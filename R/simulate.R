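#' Raw uniformly-sampled trace
#'
#' Lightweight container for a single-channel photometry (or pupil-area)
#' signal: sample `i` sits at time `t0 + (i - 1) / rate` and covers the
#' half-open interval up to the next sample.
#'
#' @param values numeric vector of samples (finite).
#' @param rate sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @return object of class `raw_trace`.
#' @export
raw_trace <- function(values, rate, t0 = 0) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop_invalid("`rate` must be a positive scalar")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_invalid("`values` must be finite numeric")
  structure(list(values = as.numeric(values), rate = rate, t0 = t0),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %d samples @ %g Hz, t0 = %g s (%.1f s)\n",
              length(x$values), x$rate, x$t0, length(x$values) / x$rate))
  invisible(x)
}

trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1) / trace$rate
}

# ---- response kernels --------------------------------------------------

#' Response kernel primitives
#'
#' `kernel_dexp` is the difference-of-exponentials (alpha-like) kernel
#' `(exp(-t/decay) - exp(-t/rise)) / M`, zero for `t < 0` and normalised so
#' its peak value is exactly 1, reached at
#' `t* = rise * decay / (decay - rise) * log(decay / rise)`.
#' `kernel_alpha` is the one-parameter limit `(t/tau) * exp(1 - t/tau)`,
#' peaking at 1 when `t = tau`. Closed-form peak times/values make these
#' kernels convenient oracles for peak/latency metrics.
#'
#' @param t time in seconds (vectorised); values before 0 give 0.
#' @param rise,decay,tau time constants in seconds (> 0, `decay != rise`).
#' @return numeric vector of kernel values in `[0, 1]`.
#' @export
kernel_dexp <- function(t, rise, decay) {
  stopifnot(rise > 0, decay > 0)
  if (abs(decay - rise) < 1e-12) return(kernel_alpha(t, rise))
  tstar <- rise * decay / (decay - rise) * log(decay / rise)
  m <- exp(-tstar / decay) - exp(-tstar / rise)
  out <- numeric(length(t))
  i <- t >= 0
  out[i] <- (exp(-t[i] / decay) - exp(-t[i] / rise)) / m
  out
}

#' @rdname kernel_dexp
#' @export
kernel_alpha <- function(t, tau) {
  stopifnot(tau > 0)
  out <- numeric(length(t))
  i <- t >= 0
  out[i] <- (t[i] / tau) * exp(1 - t[i] / tau)
  out
}

# Peak time of the normalised difference-of-exponentials kernel.
dexp_peak_time <- function(rise, decay) {
  if (abs(decay - rise) < 1e-12) return(rise)
  rise * decay / (decay - rise) * log(decay / rise)
}

# ---- parameter containers ----------------------------------------------

#' Phenomenological response-kernel parameters
#'
#' Parameters of the burst-locked response model used by the generator.
#' Each noise burst elicits (i) a dip whose amplitude is
#' `dip_slope * (intensity - 45)` z-units -- negative slope gives the
#' intensity-dependent decrease seen in the accumbens dopamine signal --
#' and (ii) a fixed-amplitude rebound after the burst. "Increase"-phenotype
#' subjects additionally show a fast positive onset transient whose
#' amplitude is multiplied by `habituation_factor^(burst - 1)` within each
#' trial, so the default 0 reproduces a first-burst-only transient
#' (second-to-first positive peak ratio approximately 0).
#'
#' All amplitudes are expressed in z-units, i.e. multiples of the baseline
#' noise standard deviation; the generator scales them by the sensor noise
#' so that baseline z-scoring recovers them whatever the raw gain.
#'
#' @param dip_slope z-units per dB (negative for decrease-type dips).
#' @param dip_latency seconds from burst onset to the start of the dip
#'   kernel (before envelope adjustment).
#' @param dip_rise_tau,dip_decay_tau dip kernel time constants (s).
#' @param rebound_amplitude z-units, intensity-independent.
#' @param rebound_delay seconds from burst onset to rebound kernel start.
#' @param onset_transient_amplitude z-units of the burst-onset positive
#'   transient (increase phenotype only).
#' @param onset_transient_tau alpha-kernel time constant of the transient (s).
#' @param habituation_factor per-burst multiplier in `[0, 1]` on the onset
#'   transient within a trial; 0 restricts it to burst 1.
#' @return list of class `kernel_params`.
#' @export
kernel_params <- function(dip_slope = -0.020,
                          dip_latency = 0.35,
                          dip_rise_tau = 0.05,
                          dip_decay_tau = 0.15,
                          rebound_amplitude = 0.4,
                          rebound_delay = 0.55,
                          onset_transient_amplitude = 3.6,
                          onset_transient_tau = 0.15,
                          habituation_factor = 0) {
  if (dip_rise_tau <= 0 || dip_decay_tau <= 0 || onset_transient_tau <= 0)
    stop_invalid("kernel time constants must be > 0")
  if (habituation_factor < 0 || habituation_factor > 1)
    stop_invalid("`habituation_factor` must lie in [0, 1]")
  structure(list(
    dip_slope = dip_slope, dip_latency = dip_latency,
    dip_rise_tau = dip_rise_tau, dip_decay_tau = dip_decay_tau,
    rebound_amplitude = rebound_amplitude, rebound_delay = rebound_delay,
    onset_transient_amplitude = onset_transient_amplitude,
    onset_transient_tau = onset_transient_tau,
    habituation_factor = habituation_factor
  ), class = "kernel_params")
}

#' Per-subject simulation parameters
#'
#' @param subject_id identifier string.
#' @param phenotype `"increase"` or `"decrease"`.
#' @param slope_deviation z/dB random effect added to the population
#'   `dip_slope` (induces the within-subject clustering the cluster-robust
#'   inference assumes).
#' @param noise_sd sensor noise sd in raw units; response amplitudes are
#'   expressed as multiples of it (z-units). 0 gives a noiseless trace in
#'   z-units directly.
#' @param drift_amplitude,drift_period slow sinusoidal baseline drift
#'   (z-units, seconds).
#' @return list of class `subject_params`.
#' @export
subject_params <- function(subject_id = "s1",
                           phenotype = c("decrease", "increase"),
                           slope_deviation = 0,
                           noise_sd = 0.3,
                           drift_amplitude = 0.1,
                           drift_period = 300) {
  phenotype <- match.arg(phenotype)
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  structure(list(subject_id = subject_id, phenotype = phenotype,
                 slope_deviation = slope_deviation, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period),
            class = "subject_params")
}

#' Cohort-level simulation configuration
#'
#' @param n_subjects number of subjects.
#' @param p_increase probability a subject is the increase phenotype.
#' @param kernel a [kernel_params()] object shared by the cohort.
#' @param between_subject_slope_sd sd (z/dB) of the Normal subject-level
#'   slope deviations.
#' @param sample_rate output sampling rate in Hz (the analyses run at the
#'   120 Hz working rate).
#' @param noise_sd,drift_amplitude,drift_period passed to every subject.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 9L,
                          p_increase = 0,
                          kernel = kernel_params(),
                          between_subject_slope_sd = 0.004,
                          sample_rate = 120,
                          noise_sd = 0.3,
                          drift_amplitude = 0.1,
                          drift_period = 300,
                          seed = NULL) {
  if (n_subjects < 1L) stop_invalid("`n_subjects` must be >= 1")
  if (p_increase < 0 || p_increase > 1)
    stop_invalid("`p_increase` must lie in [0, 1]")
  if (sample_rate <= 0) stop_invalid("`sample_rate` must be > 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 p_increase = p_increase, kernel = kernel,
                 between_subject_slope_sd = between_subject_slope_sd,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period, seed = seed),
            class = "cohort_config")
}

# ---- subject / cohort simulation ---------------------------------------

# Deterministic (noise-free, drift-free) burst-locked response of one
# subject, in z-units. `t` must be an ascending time grid; on the uniform
# simulation grid burst windows are located by index arithmetic so the cost
# stays linear in trace length. Shared by simulate_subject and by test
# oracles that evaluate the continuous-time model at arbitrary times.
response_signal <- function(t, subject, kernel, schedule, rate = NULL) {
  n <- length(t)
  out <- numeric(n)
  slope <- kernel$dip_slope + subject$slope_deviation
  env_shift <- schedule$rise_time / 2   # envelope tracking: later rise peaks later
  rel <- burst_onsets(schedule)
  n_bursts <- schedule$bursts_per_trial
  support <- 6  # seconds after burst onset beyond which kernels are negligible
  uniform <- !is.null(rate)
  t0 <- t[1]
  for (k in seq_along(schedule$trial_onsets)) {
    amp_dip <- slope * (schedule$trial_intensity[k] - 45)
    for (b in seq_len(n_bursts)) {
      o <- schedule$trial_onsets[k] + rel[b]
      if (uniform) {
        lo <- max(1L, ceiling((o - t0) * rate - 1e-9) + 1L)
        hi <- min(n, floor((o + support - t0) * rate - 1e-9) + 1L)
        if (lo > hi) next
        i <- lo:hi
      } else {
        i <- which(t >= o & t < o + support)
        if (!length(i)) next
      }
      dt <- t[i] - o
      v <- amp_dip * kernel_dexp(dt - kernel$dip_latency - env_shift,
                                 kernel$dip_rise_tau, kernel$dip_decay_tau) +
        kernel$rebound_amplitude *
          kernel_dexp(dt - kernel$rebound_delay - env_shift,
                      kernel$dip_rise_tau, kernel$dip_decay_tau)
      if (subject$phenotype == "increase") {
        h <- if (b == 1L) 1 else kernel$habituation_factor^(b - 1)
        if (h > 0)
          v <- v + kernel$onset_transient_amplitude * h *
            kernel_alpha(dt - env_shift, kernel$onset_transient_tau)
      }
      out[i] <- out[i] + v
    }
  }
  out
}

#' Simulate one subject's photometry trace
#'
#' Generates `baseline drift + burst-locked responses + white sensor noise`
#' on a uniform grid starting 0 s and ending 15 s after the last trial.
#' Response amplitudes are parameterised in z-units (multiples of
#' `noise_sd`): the raw trace is
#' `noise_sd * (drift + response) + N(0, noise_sd)`, so per-trial baseline
#' z-scoring recovers the nominal amplitudes independently of the sensor
#' gain. With `noise_sd = 0` the trace is the noiseless z-unit signal
#' itself.
#'
#' @param subject a [subject_params()] object.
#' @param kernel a [kernel_params()] object.
#' @param schedule a [make_schedule()] schedule.
#' @param rate sampling rate in Hz.
#' @param seed integer seed for the sensor noise.
#' @return a [raw_trace()].
#' @export
simulate_subject <- function(subject, kernel, schedule, rate = 120,
                             seed = NULL) {
  if (rate <= 0) stop_invalid("`rate` must be > 0")
  if (!length(schedule$trial_onsets)) stop_invalid("empty schedule")
  dur <- schedule_end(schedule) + 15
  n <- round(dur * rate)
  t <- (seq_len(n) - 1) / rate
  drift <- if (subject$drift_amplitude != 0)
    subject$drift_amplitude * sin(2 * pi * t / subject$drift_period)
  else numeric(n)
  signal <- drift + response_signal(t, subject, kernel, schedule, rate = rate)
  scale <- if (subject$noise_sd > 0) subject$noise_sd else 1
  noise <- with_seed(seed, rnorm(n, 0, subject$noise_sd))
  raw_trace(scale * signal + noise, rate = rate, t0 = 0)
}

#' Simulate a cohort with known ground truth
#'
#' Draws subject-level slope deviations `Normal(0, between_subject_slope_sd^2)`
#' and phenotypes `Bernoulli(p_increase)`, then simulates each subject's
#' trace. All randomness derives from `config$seed`, so a fixed seed yields
#' a bit-identical cohort.
#'
#' @param config a [cohort_config()].
#' @param schedule a [make_schedule()] schedule.
#' @return list with elements `subjects` (list of [subject_params()], the
#'   ground truth) and `traces` (list of [raw_trace()]), both named by
#'   subject id.
#' @export
simulate_cohort <- function(config, schedule) {
  n <- config$n_subjects
  draws <- with_seed(config$seed, list(
    dev = rnorm(n, 0, config$between_subject_slope_sd),
    inc = runif(n) < config$p_increase
  ))
  ids <- sprintf("s%02d", seq_len(n))
  subjects <- traces <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- subject_params(
      subject_id = ids[i],
      phenotype = if (draws$inc[i]) "increase" else "decrease",
      slope_deviation = draws$dev[i],
      noise_sd = config$noise_sd,
      drift_amplitude = config$drift_amplitude,
      drift_period = config$drift_period)
    traces[[i]] <- simulate_subject(
      subjects[[i]], config$kernel, schedule,
      rate = config$sample_rate, seed = derive_seed(config$seed, i))
  }
  names(subjects) <- names(traces) <- ids
  list(subjects = subjects, traces = traces)
}

#' Simulate a pupil-area series
#'
#' Slow intensity-scaled dilation during each 10-s stimulus window on a
#' 30 frames/s grid. The dilation kernel is an alpha kernel normalised so
#' its mean over the stimulus window is 1; the noiseless mean z-response to
#' intensity `I` is therefore exactly `gain * (I - 45)`. The default gain
#' calibrates the 105-dB response to a mean z of 0.33.
#'
#' @param onsets stimulus onset times (s).
#' @param intensities dB SPL per stimulus.
#' @param rate frame rate, 30 Hz by default.
#' @param gain z-units per dB above the 45-dB anchor.
#' @param duration stimulus duration (s).
#' @param tau dilation kernel time constant (s).
#' @param noise_sd frame noise in z-units (same scaling convention as
#'   [simulate_subject()]).
#' @param seed integer seed.
#' @return a [raw_trace()] of pupil area (arbitrary units).
#' @export
simulate_pupil <- function(onsets, intensities, rate = 30,
                           gain = 0.33 / 60, duration = 10, tau = 3,
                           noise_sd = 0, seed = NULL) {
  stopifnot(length(onsets) == length(intensities), rate > 0)
  dur <- max(onsets) + duration + 10
  n <- round(dur * rate)
  t <- (seq_len(n) - 1) / rate
  # normalise the kernel's mean over [0, duration) to 1
  tg <- (seq_len(round(duration * rate)) - 1) / rate
  k_mean <- mean(kernel_alpha(tg, tau))
  signal <- numeric(n)
  for (k in seq_along(onsets)) {
    i <- which(t >= onsets[k] & t < onsets[k] + duration + 5 * tau)
    signal[i] <- signal[i] +
      gain * (intensities[k] - 45) * kernel_alpha(t[i] - onsets[k], tau) / k_mean
  }
  scale <- if (noise_sd > 0) noise_sd else 1
  noise <- with_seed(seed, rnorm(n, 0, noise_sd))
  raw_trace(100 + scale * signal + noise, rate = rate, t0 = 0)
}
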