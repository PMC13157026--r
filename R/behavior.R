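#' Two-compartment zone layout
#'
#' Two axis-aligned rectangles (Zone A, Zone B) partitioning the arena.
#' Each rectangle is `c(xmin, xmax, ymin, ymax)` in cm; membership uses
#' half-open intervals on x so the shared boundary belongs to exactly one
#' zone.
#'
#' @param zone_a,zone_b numeric `c(xmin, xmax, ymin, ymax)`.
#' @return list of class `zone_layout`.
#' @export
zone_layout <- function(zone_a = c(0, 30, 0, 30),
                        zone_b = c(30, 60, 0, 30)) {
  stopifnot(length(zone_a) == 4L, length(zone_b) == 4L)
  structure(list(zone_a = zone_a, zone_b = zone_b), class = "zone_layout")
}

in_rect <- function(x, y, r) {
  x >= r[1] & x < r[2] & y >= r[3] & y <= r[4]
}

#' Time-weighted zone occupancy
#'
#' Percentage of session time spent in each compartment. Each inter-sample
#' interval is weighted by its duration and assigned to the zone of the
#' earlier sample (the tracker's semantics are unspecified, so the simplest
#' piecewise-constant reading is used); the final sample extends to the
#' session end. The two percentages sum to 100 exactly.
#'
#' @param track data.frame with columns `t_s`, `x_cm`, `y_cm`, timestamps
#'   strictly increasing.
#' @param layout a [zone_layout()].
#' @param session `c(start, end)` window in seconds (half-open).
#' @return named numeric `c(zone_a = , zone_b = )` percentages.
#' @export
zone_occupancy <- function(track, layout, session = range(track$t_s)) {
  stopifnot(all(c("t_s", "x_cm", "y_cm") %in% names(track)))
  if (session[2] <= session[1]) stop_invalid("empty session window")
  if (any(diff(track$t_s) <= 0))
    stop_invalid("track timestamps must be strictly increasing")
  i <- which(track$t_s >= session[1] & track$t_s < session[2])
  if (!length(i)) stop_invalid("no track samples inside the session window")
  t <- track$t_s[i]
  dt <- c(diff(t), session[2] - t[length(t)])
  a <- in_rect(track$x_cm[i], track$y_cm[i], layout$zone_a)
  ta <- sum(dt[a]); tb <- sum(dt[!a])
  tot <- ta + tb
  c(zone_a = 100 * ta / tot, zone_b = 100 * tb / tot)
}

#' Mean pupil z-response per stimulus
#'
#' Per-trial z-scoring of the pupil-area series against the 5 s before each
#' onset (same normalisation as the photometry traces), then the mean z over
#' the 10-s stimulus window.
#'
#' @param series a [raw_trace()] of pupil area (30 frames/s typically).
#' @param onsets stimulus onset times (s).
#' @param duration stimulus duration (s).
#' @param baseline_dur baseline duration (s).
#' @param normalize if `FALSE`, subtract the baseline mean only (noiseless
#'   synthetic series have zero baseline sd).
#' @return numeric vector: mean z during the stimulus window, one per onset.
#' @export
pupil_response <- function(series, onsets, duration = 10,
                           baseline_dur = 5, normalize = TRUE) {
  aligned <- zscore_by_trial(series, onsets,
                             baseline_dur = baseline_dur,
                             segment = c(baseline_dur, duration),
                             normalize = normalize)
  sel <- aligned$rel_time >= 0 & aligned$rel_time < duration
  rowMeans(aligned$z[, sel, drop = FALSE])
}
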