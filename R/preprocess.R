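#' Downsample a trace onto a uniform grid
#'
#' Anti-aliased downsampling to the 120 Hz working rate: a centred boxcar
#' low-pass (width `round(rate / target_rate)` samples, forced odd, edges
#' padded by replication) followed by linear interpolation onto the uniform
#' target grid spanning the same time range. Both steps are linear, so
#' `resample_uniform(a * x + b) = a * resample_uniform(x) + b`, and a
#' constant trace is preserved exactly. Upsampling is refused.
#'
#' @param raw a [raw_trace()].
#' @param target_rate output rate in Hz, `<= raw$rate`.
#' @return a [raw_trace()] at `target_rate`.
#' @export
resample_uniform <- function(raw, target_rate) {
  stopifnot(inherits(raw, "raw_trace"))
  if (target_rate > raw$rate)
    stop_invalid("target_rate (%g) exceeds input rate (%g): no upsampling",
                 target_rate, raw$rate)
  x <- raw$values
  if (target_rate < raw$rate) {
    w <- round(raw$rate / target_rate)
    if (w %% 2 == 0) w <- w + 1
    if (w >= 3) {
      h <- (w - 1) / 2
      n <- length(x)
      # antisymmetric (odd) reflection keeps linear trends exact at the
      # edges, so boundary samples are not biased by the smoothing
      padded <- c(2 * x[1] - x[(h + 1):2], x, 2 * x[n] - x[(n - 1):(n - h)])
      x <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))
      x <- x[(h + 1):(h + n)]
    }
  }
  t_in <- trace_times(raw)
  span <- (length(raw$values) - 1) / raw$rate
  n_out <- floor(span * target_rate) + 1
  t_out <- raw$t0 + (seq_len(n_out) - 1) / target_rate
  y <- approx(t_in, x, xout = t_out, rule = 2)$y
  raw_trace(y, rate = target_rate, t0 = raw$t0)
}

#' Trial-aligned baseline z-scoring
#'
#' Cuts a segment `[-pre, +post)` around every trial onset and normalises it
#' into z-scores using the mean and standard deviation of the
#' `baseline_dur` seconds immediately before the onset (5 s in the standard
#' analysis). With the default `pre = baseline_dur` the baseline samples are
#' part of the segment, so each returned trial has baseline mean 0 and sd 1
#' by construction.
#'
#' @param raw a [raw_trace()], already at the working rate.
#' @param trial_onsets trial onset times in seconds.
#' @param intensity optional per-trial labels (dB) carried through.
#' @param baseline_dur baseline duration in seconds.
#' @param segment `c(pre, post)`: seconds before / after onset; the segment
#'   is the half-open window `[-pre, +post)`.
#' @param normalize if `FALSE`, only the baseline mean is subtracted
#'   (useful for noiseless synthetic traces whose baseline sd is 0).
#' @return object of class `aligned_trials`: list with `z` (trials x
#'   samples matrix), `rel_time` (s, relative to onset), `intensity`,
#'   `rate`.
#' @export
zscore_by_trial <- function(raw, trial_onsets, intensity = NULL,
                            baseline_dur = 5, segment = c(5, 10),
                            normalize = TRUE) {
  stopifnot(inherits(raw, "raw_trace"))
  rate <- raw$rate
  pre <- segment[1]; post <- segment[2]
  if (pre < 0 || post <= 0) stop_invalid("invalid segment window")
  nb <- round(baseline_dur * rate)
  nseg <- round((pre + post) * rate)
  npre <- round(pre * rate)
  x <- raw$values
  n <- length(x)
  z <- matrix(NA_real_, nrow = length(trial_onsets), ncol = nseg)
  for (k in seq_along(trial_onsets)) {
    i_on <- round((trial_onsets[k] - raw$t0) * rate) + 1L
    if (i_on - nb < 1L)
      stop_invalid("trial %d: fewer than %g s of pre-onset samples",
                   k, baseline_dur)
    if (i_on - npre < 1L || i_on + nseg - npre - 1L > n)
      stop_invalid("trial %d: segment window outside the trace", k)
    base <- x[(i_on - nb):(i_on - 1L)]
    mu <- mean(base)
    if (normalize) {
      sdv <- sd(base)
      if (!is.finite(sdv) || sdv <= 0)
        stop_invalid("trial %d: degenerate baseline (sd = 0)", k)
    } else sdv <- 1
    seg <- x[(i_on - npre):(i_on - npre + nseg - 1L)]
    z[k, ] <- (seg - mu) / sdv
  }
  structure(list(
    z = z,
    rel_time = (seq_len(nseg) - 1) / rate - pre,
    intensity = if (is.null(intensity)) rep(NA_real_, length(trial_onsets))
                else as.numeric(intensity),
    rate = rate
  ), class = "aligned_trials")
}

#' @export
print.aligned_trials <- function(x, ...) {
  cat(sprintf("<aligned_trials> %d trials x %d samples @ %g Hz, rel_time [%g, %g) s\n",
              nrow(x$z), ncol(x$z), x$rate, x$rel_time[1],
              x$rel_time[length(x$rel_time)] + 1 / x$rate))
  invisible(x)
}

#' Centred moving-median smoothing
#'
#' 200-ms moving median used for trace presentation. The window length
#' `round(window * rate)` is forced odd so the median is centred; at the
#' edges the window is truncated to the available samples.
#'
#' @param x numeric series.
#' @param window window length in seconds.
#' @param rate sampling rate in Hz.
#' @return numeric vector, same length as `x`.
#' @export
moving_median <- function(x, window = 0.2, rate) {
  if (!length(x)) stop_invalid("empty input")
  k <- round(window * rate)
  if (k < 1) stop_invalid("window shorter than one sample")
  if (k %% 2 == 0) k <- k + 1
  n <- length(x)
  if (k >= 2 * n) k <- 2 * (n - 1) + 1
  h <- (k - 1) / 2
  if (h == 0) return(x)
  out <- if (n >= k) as.numeric(stats::runmed(x, k, endrule = "keep"))
         else x
  edge <- seq_len(min(h, n))
  for (i in edge) out[i] <- median(x[seq_len(min(n, i + h))])
  for (i in (n - edge + 1)) out[i] <- median(x[max(1, i - h):n])
  out
}

#' Average aligned trials by intensity
#'
#' Pointwise arithmetic mean of the z-scored trials sharing each intensity
#' label (the per-intensity average traces of the figures).
#'
#' @param aligned an `aligned_trials` object.
#' @param intensities intensities to average; defaults to all present.
#' @return matrix intensities x samples with `dimnames` giving the
#'   intensity, and attributes `rel_time` and `rate`.
#' @export
average_trials <- function(aligned, intensities = NULL) {
  stopifnot(inherits(aligned, "aligned_trials"))
  if (is.null(intensities)) intensities <- sort(unique(aligned$intensity))
  out <- matrix(NA_real_, nrow = length(intensities), ncol = ncol(aligned$z),
                dimnames = list(as.character(intensities), NULL))
  for (j in seq_along(intensities)) {
    rows <- which(aligned$intensity == intensities[j])
    if (!length(rows))
      stop_invalid("no trials at intensity %g dB", intensities[j])
    out[j, ] <- colMeans(aligned$z[rows, , drop = FALSE])
  }
  attr(out, "rel_time") <- aligned$rel_time
  attr(out, "rate") <- aligned$rate
  out
}

#' Cut per-burst segments out of a trial-relative trace
#'
#' Half-open windows `[onset, onset + window)` on the trial-relative time
#' axis, one row per burst, order preserved. With the standard 10 bursts at
#' 1-s spacing and a 1-s window the 10 segments tile `[0, 10)` exactly.
#'
#' @param trace numeric trace on the `rel_time` axis (e.g. one row of
#'   [average_trials()]).
#' @param burst_onsets burst onsets in trial-relative seconds.
#' @param window window length in seconds (> 0).
#' @param rate sampling rate; defaults to the trace's `rate` attribute.
#' @param rel_time time axis; defaults to the trace's `rel_time` attribute.
#' @return matrix bursts x samples.
#' @export
segment_bursts <- function(trace, burst_onsets, window = 1.0,
                           rate = attr(trace, "rate"),
                           rel_time = attr(trace, "rel_time")) {
  if (is.null(rate) || is.null(rel_time))
    stop_invalid("`rate` and `rel_time` must be supplied or attached")
  if (window <= 0) stop_invalid("`window` must be > 0")
  nw <- round(window * rate)
  t0 <- rel_time[1]
  out <- matrix(NA_real_, nrow = length(burst_onsets), ncol = nw)
  for (b in seq_along(burst_onsets)) {
    i0 <- round((burst_onsets[b] - t0) * rate) + 1L
    if (i0 < 1L || i0 + nw - 1L > length(trace))
      stop_invalid("burst %d: window [%g, %g) overruns the trace",
                   b, burst_onsets[b], burst_onsets[b] + window)
    out[b, ] <- trace[i0:(i0 + nw - 1L)]
  }
  out
}
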