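#' Trace CSV I/O
#'
#' Traces are stored as two-column CSV (`time_s`, `value`); the sampling
#' rate is recovered from the time stamps on read (the grid must be
#' uniform).
#'
#' @param trace a [raw_trace()].
#' @param path file path.
#' @return `read_trace_csv` returns a [raw_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  df <- data.frame(time_s = trace_times(trace), value = trace$values)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(df)))
  dt <- diff(df$time_s)
  if (max(dt) - min(dt) > 1e-6)
    stop_invalid("trace in %s is not uniformly sampled", path)
  raw_trace(df$value, rate = 1 / mean(dt), t0 = df$time_s[1])
}

#' Tidy metrics table across subjects
#'
#' One row per (subject, intensity, response_type, measure): the flat CSV
#' layout consumed by the trend CLI and external tools.
#'
#' @param summaries list of [summarize_subject()] results.
#' @return data.frame with columns `subject_id`, `intensity`,
#'   `response_type` (`first`/`average`), `measure` (`min`/`max`),
#'   `value`, `latency`.
#' @export
metrics_table <- function(summaries) {
  rows <- lapply(summaries, function(s) {
    tb <- s$table
    do.call(rbind, list(
      data.frame(subject_id = s$subject_id, intensity = tb$intensity,
                 response_type = "first", measure = "min",
                 value = tb$first_min, latency = tb$first_neg_latency),
      data.frame(subject_id = s$subject_id, intensity = tb$intensity,
                 response_type = "first", measure = "max",
                 value = tb$first_max, latency = tb$first_pos_latency),
      data.frame(subject_id = s$subject_id, intensity = tb$intensity,
                 response_type = "average", measure = "min",
                 value = tb$avg_min, latency = tb$avg_neg_latency),
      data.frame(subject_id = s$subject_id, intensity = tb$intensity,
                 response_type = "average", measure = "max",
                 value = tb$avg_max, latency = tb$avg_pos_latency)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

trend_fit_record <- function(fit) {
  list(beta = fit$beta, intercept = fit$intercept, cr_se = fit$cr_se,
       t = fit$t_stat, p = fit$p_boot,
       ci_lo = if (!is.null(fit$ci)) fit$ci[1] else NULL,
       ci_hi = if (!is.null(fit$ci)) fit$ci[2] else NULL,
       B = fit$B, seed = fit$seed, n_clusters = fit$n_clusters)
}

#' Serialize a result bundle
#'
#' Writes `schedule.csv`, `metrics.csv`, `phenotypes.csv`, `trends.json`
#' and `log.txt` (every seed and analysis flag, for provenance) into
#' `dir`.
#'
#' @param bundle result of [run_noise_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_schedule_csv(bundle$schedule, file.path(dir, "schedule.csv"))
  write.csv(metrics_table(bundle$summaries),
            file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(bundle$phenotypes, file.path(dir, "phenotypes.csv"),
            row.names = FALSE)
  trends <- lapply(bundle$trends, function(group)
    lapply(group, trend_fit_record))
  jsonlite::write_json(trends, file.path(dir, "trends.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- bundle$config
  flags <- vapply(cfg[setdiff(names(cfg), c("kernel", "out_dir"))],
                  function(v) paste(format(v), collapse = ","), "")
  writeLines(c(sprintf("photodyn run %s", format(Sys.time(), "%Y-%m-%d")),
               sprintf("%s = %s", names(flags), flags),
               sprintf("kernel.%s = %g", names(cfg$kernel),
                       unlist(cfg$kernel))),
             file.path(dir, "log.txt"))
  invisible(dir)
}

#' Run-configuration JSON I/O
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `read_run_config` returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$kernel <- unclass(x$kernel)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kernel <- do.call(kernel_params, as.list(x$kernel))
  x$kernel <- NULL
  cfg <- do.call(run_config, c(x, list(kernel = kernel)))
  cfg
}
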