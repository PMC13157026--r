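#' Build a noise-burst stimulus schedule
#'
#' Constructs the trial timeline of a noise-burst presentation experiment:
#' one 10-s trial per requested intensity presentation, each trial a train of
#' `bursts_per_trial` bursts at `burst_period` spacing (500 ms on / 500 ms
#' off by default), with inter-trial intervals drawn i.i.d. from
#' `isi_choices`. The first trial starts after one ISI draw, so at least 5 s
#' of pre-trial baseline always exists.
#'
#' The standard intensity series of the burst experiments is a fixed order,
#' ten presentations per level: `rep(c(45, 65, 85, 105), each = 10)`.
#'
#' @param intensities numeric vector of per-trial sound intensities (dB SPL),
#'   in presentation order; one trial is generated per element.
#' @param envelope burst intensity envelope kind: `"flat"` (5 ms linear
#'   rise/fall), `"ramped"` (495 ms rise / 5 ms fall) or `"damped"`
#'   (5 ms rise / 495 ms fall).
#' @param isi_choices candidate inter-trial intervals in seconds; the
#'   experiment draws from 25, 30 or 35 s.
#' @param seed integer seed for the ISI draws (reproducible schedules).
#' @param bursts_per_trial,burst_period,burst_duration train geometry;
#'   defaults give 10 x (0.5 s on / 0.5 s off) = 10 s per trial.
#' @return An object of class `stim_schedule`: a list with fields
#'   `trial_onsets` (s), `trial_intensity` (dB), `bursts_per_trial`,
#'   `burst_period` (s), `burst_duration` (s), `envelope`, `rise_time` (s),
#'   `fall_time` (s).
#' @examples
#' sch <- make_schedule(c(45, 65, 85, 105), seed = 1)
#' diff(sch$trial_onsets) - 10  # ISIs, each in {25, 30, 35}
#' @export
make_schedule <- function(intensities,
                          envelope = c("flat", "ramped", "damped"),
                          isi_choices = c(25, 30, 35),
                          seed = NULL,
                          bursts_per_trial = 10L,
                          burst_period = 1.0,
                          burst_duration = 0.5) {
  envelope <- match.arg(envelope)
  if (length(intensities) == 0L || !is.numeric(intensities))
    stop_invalid("`intensities` must be a non-empty numeric vector")
  if (length(isi_choices) == 0L || any(!is.finite(isi_choices)) ||
      any(isi_choices <= 0))
    stop_invalid("`isi_choices` must be positive and non-empty")
  n <- length(intensities)
  isis <- with_seed(seed, {
    isi_choices[sample.int(length(isi_choices), n, replace = TRUE)]
  })
  trial_len <- bursts_per_trial * burst_period
  onsets <- cumsum(isis) + trial_len * (seq_len(n) - 1L)
  rf <- envelope_rise_fall(envelope, burst_duration)
  structure(list(
    trial_onsets = onsets,
    trial_intensity = as.numeric(intensities),
    bursts_per_trial = as.integer(bursts_per_trial),
    burst_period = burst_period,
    burst_duration = burst_duration,
    envelope = envelope,
    rise_time = rf[["rise"]],
    fall_time = rf[["fall"]]
  ), class = "stim_schedule")
}

# Default rise/fall times per envelope kind (seconds).
envelope_rise_fall <- function(kind, duration = 0.5) {
  switch(kind,
    flat   = c(rise = 0.005, fall = 0.005),
    ramped = c(rise = duration - 0.005, fall = 0.005),
    damped = c(rise = 0.005, fall = duration - 0.005),
    stop_invalid("unknown envelope kind '%s'", kind)
  )
}

#' Sampled burst intensity envelope
#'
#' Piecewise-linear on/off envelope of a single noise burst: linear 0 to 1
#' over `rise`, flat at 1, linear 1 to 0 over `fall`. Sample `i` covers the
#' half-open interval `[(i-1)/rate, i/rate)` and takes the envelope value at
#' its left edge.
#'
#' @param kind one of `"flat"`, `"ramped"`, `"damped"`; supplies default
#'   rise/fall times when they are not given.
#' @param duration burst duration in seconds (0.5 by default).
#' @param rise,fall linear rise and fall times in seconds;
#'   `rise + fall <= duration`.
#' @param rate sampling rate in Hz.
#' @return numeric vector of length `round(duration * rate)` with values in
#'   `[0, 1]`.
#' @examples
#' env <- burst_envelope("ramped", rate = 1000)
#' which.max(env)  # peak reached at t = 0.495 s
#' @export
burst_envelope <- function(kind = c("flat", "ramped", "damped"),
                           duration = 0.5, rise = NULL, fall = NULL,
                           rate) {
  kind <- match.arg(kind)
  if (!is.numeric(rate) || rate <= 0) stop_invalid("`rate` must be > 0")
  rf <- envelope_rise_fall(kind, duration)
  if (is.null(rise)) rise <- rf[["rise"]]
  if (is.null(fall)) fall <- rf[["fall"]]
  if (rise < 0 || fall < 0 || rise + fall > duration + 1e-12)
    stop_invalid("rise + fall must not exceed the burst duration")
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  env <- rep(1, n)
  if (rise > 0) {
    i <- t < rise
    env[i] <- t[i] / rise
  }
  if (fall > 0) {
    i <- t >= duration - fall
    env[i] <- (duration - t[i]) / fall
  }
  pmin(pmax(env, 0), 1)
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf(
    "<stim_schedule> %d trials, %s envelope, %d x %.2f s bursts/trial\n",
    length(x$trial_onsets), x$envelope, x$bursts_per_trial, x$burst_duration))
  cat(sprintf("  intensities: %s dB\n",
              paste(unique(x$trial_intensity), collapse = ", ")))
  cat(sprintf("  span: %.1f .. %.1f s\n", x$trial_onsets[1], schedule_end(x)))
  invisible(x)
}

#' Within-trial burst onsets
#'
#' @param schedule a `stim_schedule`.
#' @param relative if `TRUE` (default) return onsets relative to trial onset
#'   (`0, 1, ..., 9` s for the standard train); otherwise a matrix of
#'   absolute onsets, trials in rows.
#' @return numeric vector (relative) or matrix (absolute).
#' @export
burst_onsets <- function(schedule, relative = TRUE) {
  rel <- (seq_len(schedule$bursts_per_trial) - 1) * schedule$burst_period
  if (relative) return(rel)
  outer(schedule$trial_onsets, rel, `+`)
}

trial_length <- function(schedule) {
  schedule$bursts_per_trial * schedule$burst_period
}

schedule_end <- function(schedule) {
  max(schedule$trial_onsets) + trial_length(schedule)
}

#' Write / read a schedule as CSV
#'
#' The on-disk dialect is one row per trial with columns `trial_index`,
#' `onset_s`, `intensity_db`, `envelope`; train geometry and rise/fall times
#' travel in commented header lines so a schedule round-trips exactly.
#'
#' @param schedule a `stim_schedule`.
#' @param path file path.
#' @return `read_schedule_csv` returns a `stim_schedule`;
#'   `write_schedule_csv` returns `path` invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# bursts_per_trial=%d burst_period=%g burst_duration=%g rise_time=%g fall_time=%g",
    schedule$bursts_per_trial, schedule$burst_period,
    schedule$burst_duration, schedule$rise_time, schedule$fall_time), con)
  writeLines("trial_index,onset_s,intensity_db,envelope", con)
  writeLines(sprintf("%d,%.10g,%g,%s",
                     seq_along(schedule$trial_onsets),
                     schedule$trial_onsets, schedule$trial_intensity,
                     schedule$envelope), con)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  geom <- as.numeric(regmatches(hdr, gregexpr("[0-9.]+", hdr))[[1]])
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(list(
    trial_onsets = df$onset_s,
    trial_intensity = df$intensity_db,
    bursts_per_trial = as.integer(geom[1]),
    burst_period = geom[2],
    burst_duration = geom[3],
    envelope = df$envelope[1],
    rise_time = geom[4],
    fall_time = geom[5]
  ), class = "stim_schedule")
}
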