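#' Extrema and latencies within a half-open window
#'
#' Minimum and maximum of `series` over the window `[a, b)` on its time
#' axis, with latencies measured from the window start. Ties are broken by
#' first occurrence.
#'
#' @param series numeric trace.
#' @param rate sampling rate in Hz.
#' @param window `c(a, b)` in the series' time units, `a < b`.
#' @param t0 time of the first sample (defaults to the `rel_time` attribute
#'   start, else 0).
#' @return list with `min_z`, `neg_latency`, `max_z`, `pos_latency`.
#' @export
extrema_in_window <- function(series, rate, window, t0 = NULL) {
  if (is.null(t0)) {
    rt <- attr(series, "rel_time")
    t0 <- if (!is.null(rt)) rt[1] else 0
  }
  if (length(window) != 2L || window[2] <= window[1])
    stop_invalid("`window` must be c(a, b) with a < b")
  i0 <- round((window[1] - t0) * rate) + 1L
  i1 <- ceiling((window[2] - t0) * rate - 1e-9)  # last sample strictly before b
  i1 <- i1 + 0L
  if (i0 < 1L || i1 > length(series) || i1 < i0)
    stop_invalid("window [%g, %g) outside the series", window[1], window[2])
  seg <- series[i0:i1]
  imin <- which.min(seg)
  imax <- which.max(seg)
  list(min_z = seg[imin], neg_latency = (imin - 1) / rate,
       max_z = seg[imax], pos_latency = (imax - 1) / rate)
}

#' Per-burst response metrics
#'
#' For each noise burst: the z-score at burst onset, the extrema over the
#' 1-s burst window (burst plus the silent gap where the rebound occurs),
#' their latencies from burst onset, and the absolute z-score amplitudes --
#' the absolute difference between the onset z and each peak, the onset
#' value serving as the per-burst baseline.
#'
#' @param avg_trace trace on the trial-relative axis (one row of
#'   [average_trials()], attributes attached).
#' @param burst_onsets burst onsets in trial-relative seconds.
#' @param window burst window length in seconds.
#' @param rate,rel_time axis description; default to the trace attributes.
#' @return data.frame, one row per burst: `burst_index`, `onset_z`,
#'   `min_z`, `max_z`, `neg_latency`, `pos_latency`, `neg_amplitude`,
#'   `pos_amplitude`.
#' @export
burst_metrics <- function(avg_trace, burst_onsets, window = 1.0,
                          rate = attr(avg_trace, "rate"),
                          rel_time = attr(avg_trace, "rel_time")) {
  segs <- segment_bursts(avg_trace, burst_onsets, window = window,
                         rate = rate, rel_time = rel_time)
  imin <- apply(segs, 1L, which.min)
  imax <- apply(segs, 1L, which.max)
  nb <- length(burst_onsets)
  onset_z <- segs[, 1]
  min_z <- segs[cbind(seq_len(nb), imin)]
  max_z <- segs[cbind(seq_len(nb), imax)]
  data.frame(
    burst_index = seq_len(nb),
    onset_z = onset_z, min_z = min_z, max_z = max_z,
    neg_latency = (imin - 1) / rate,
    pos_latency = (imax - 1) / rate,
    neg_amplitude = abs(onset_z - min_z),
    pos_amplitude = abs(max_z - onset_z))
}

#' Second-to-first peak ratio
#'
#' Ratio of the second-burst to the first-burst peak deviation (N2/N1 on
#' negative peaks, P2/P1 on positive peaks), computed on signed peak values
#' relative to onset so that equal dips give a ratio near +1 and an absent
#' second transient gives a ratio near 0. If the first peak is smaller than
#' `eps` in magnitude the ratio is undefined and `NA` is returned.
#'
#' @param second,first signed peak deviations (z-units).
#' @param eps magnitude guard for the denominator.
#' @return numeric ratio, or `NA_real_` when undefined.
#' @export
peak_ratio <- function(second, first, eps = 1e-6) {
  if (!is.finite(first) || abs(first) < eps) return(NA_real_)
  second / first
}

#' Increase/decrease phenotype classification
#'
#' A subject is the "increase" phenotype when the trial-averaged maximum
#' z-score strictly exceeds `threshold` (2.58 by default) at any tested
#' intensity; otherwise "decrease". A maximum exactly at the threshold is
#' "decrease".
#'
#' @param max_z numeric vector: per-intensity maxima of the trial-averaged
#'   trace during noise presentation, or a [summarize_subject()] result.
#' @param threshold classification threshold in z-units.
#' @return `"increase"` or `"decrease"`.
#' @export
classify_subject <- function(max_z, threshold = 2.58) {
  if (inherits(max_z, "subject_summary")) max_z <- max_z$table$window_max
  if (!length(max_z) || any(!is.finite(max_z)))
    stop_invalid("`max_z` must be non-empty and finite")
  if (any(max_z > threshold)) "increase" else "decrease"
}

#' Per-subject response summary
#'
#' The per-intensity summary the trend analyses consume. For each
#' intensity: trials are averaged into one trace; `first_min` / `first_max`
#' are the extrema of the burst-1 window of that trace; `avg_min` /
#' `avg_max` are the extrema of the pointwise mean of the per-burst
#' segments; `window_max` / `window_min` are the extrema of the averaged
#' trace over the whole noise window `[0, 10)` and drive the phenotype
#' classification.
#'
#' @param aligned an `aligned_trials` object for one subject.
#' @param schedule the [make_schedule()] schedule (burst geometry).
#' @param subject_id identifier carried into the output.
#' @param burst_window per-burst window length (s).
#' @param threshold classification threshold (z).
#' @return object of class `subject_summary`: list with `subject_id`,
#'   `table` (data.frame per intensity), `phenotype`.
#' @export
summarize_subject <- function(aligned, schedule, subject_id = "s1",
                              burst_window = 1.0, threshold = 2.58) {
  intensities <- sort(unique(aligned$intensity))
  avg <- average_trials(aligned, intensities)
  rate <- aligned$rate
  rel <- burst_onsets(schedule)
  trial_len <- trial_length(schedule)
  nI <- length(intensities)
  z <- rep(NA_real_, nI)
  tab <- data.frame(intensity = intensities,
                    first_min = z, first_max = z,
                    first_neg_latency = z, first_pos_latency = z,
                    avg_min = z, avg_max = z,
                    avg_neg_latency = z, avg_pos_latency = z,
                    window_min = z, window_max = z)
  for (j in seq_along(intensities)) {
    tr <- avg[j, ]
    attr(tr, "rel_time") <- aligned$rel_time
    attr(tr, "rate") <- rate
    e1 <- extrema_in_window(tr, rate, c(rel[1], rel[1] + burst_window))
    ew <- extrema_in_window(tr, rate, c(0, trial_len))
    segs <- segment_bursts(tr, rel, window = burst_window)
    seg_mean <- colMeans(segs)
    tab$first_min[j] <- e1$min_z
    tab$first_max[j] <- e1$max_z
    tab$first_neg_latency[j] <- e1$neg_latency
    tab$first_pos_latency[j] <- e1$pos_latency
    tab$avg_min[j] <- min(seg_mean)
    tab$avg_max[j] <- max(seg_mean)
    tab$avg_neg_latency[j] <- (which.min(seg_mean) - 1) / rate
    tab$avg_pos_latency[j] <- (which.max(seg_mean) - 1) / rate
    tab$window_min[j] <- ew$min_z
    tab$window_max[j] <- ew$max_z
  }
  structure(list(subject_id = subject_id, table = tab,
                 phenotype = classify_subject(tab$window_max, threshold)),
            class = "subject_summary")
}

#' @export
print.subject_summary <- function(x, ...) {
  cat(sprintf("<subject_summary> %s, phenotype: %s\n",
              x$subject_id, x$phenotype))
  print(x$table[, c("intensity", "first_min", "first_max",
                    "avg_min", "avg_max", "window_max")], ...)
  invisible(x)
}

#' Assemble the long table for trend inference
#'
#' Tidy (subject, intensity, value) rows for one measure/response
#' combination across a list of subject summaries, the input of
#' [fit_cluster_ols()].
#'
#' @param summaries list of [summarize_subject()] results.
#' @param measure `"min"` or `"max"`.
#' @param response `"first"` (burst-1 window) or `"average"` (across-burst
#'   mean segment).
#' @param phenotype optionally restrict to one phenotype.
#' @return data.frame with columns `subject_id`, `intensity`, `value`.
#' @export
build_long_table <- function(summaries, measure = c("min", "max"),
                             response = c("average", "first"),
                             phenotype = NULL) {
  measure <- match.arg(measure)
  response <- match.arg(response)
  col <- paste0(if (response == "first") "first_" else "avg_", measure)
  rows <- lapply(summaries, function(s) {
    if (!is.null(phenotype) && s$phenotype != phenotype) return(NULL)
    data.frame(subject_id = s$subject_id,
               intensity = s$table$intensity,
               value = s$table[[col]])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop_invalid("no subjects matching the requested phenotype")
  rownames(out) <- NULL
  out
}
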