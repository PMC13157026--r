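# Independent oracles and fixture builders shared across the suite.

# Explicit-loop cluster sandwich: forms X, (X'X)^-1, per-cluster score outer
# products and the CR1 small-sample factor from scratch, no matrix shortcuts.
oracle_cluster_ols <- function(data) {
  X <- cbind(1, data$intensity)
  y <- data$value
  XtX <- matrix(0, 2, 2)
  Xty <- numeric(2)
  for (i in seq_len(nrow(X))) {
    XtX <- XtX + X[i, ] %o% X[i, ]
    Xty <- Xty + X[i, ] * y[i]
  }
  beta <- solve(XtX, Xty)
  e <- y - X %*% beta
  ids <- unique(data$subject_id)
  G <- length(ids)
  N <- nrow(X)
  meat <- matrix(0, 2, 2)
  for (id in ids) {
    s <- c(0, 0)
    for (i in which(data$subject_id == id)) s <- s + X[i, ] * e[i]
    meat <- meat + s %o% s
  }
  cc <- (G / (G - 1)) * ((N - 1) / (N - 2))
  V <- cc * solve(XtX) %*% meat %*% solve(XtX)
  list(beta = beta[2], intercept = beta[1], cr_se = sqrt(V[2, 2]))
}

# Clustered long-table generator for the inference calibration checks:
# subject random intercepts (sd 0.3 z) + i.i.d. Gaussian residuals (sd 0.2 z)
# around a linear intensity trend.
gen_long_table <- function(G = 9, slope = 0, icc_sd = 0.3, noise_sd = 0.2,
                           intensities = c(45, 65, 85, 105), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(intensities)
  data.frame(
    subject_id = rep(sprintf("s%02d", seq_len(G)), each = k),
    intensity = rep(intensities, G),
    value = rep(rnorm(G, 0, icc_sd), each = k) +
      slope * rep(intensities, G) + rnorm(G * k, 0, noise_sd))
}

# Continuous-time response model written out independently of the package
# internals: normalised difference-of-exponentials dip + rebound, alpha
# transient, envelope tracked as a rise/2 latency shift.
oracle_response <- function(t, kernel, schedule, slope_deviation = 0,
                            phenotype = "decrease") {
  dexp <- function(u, r, dc) {
    ts <- r * dc / (dc - r) * log(dc / r)
    m <- exp(-ts / dc) - exp(-ts / r)
    ifelse(u >= 0, (exp(-u / dc) - exp(-u / r)) / m, 0)
  }
  alpha <- function(u, tau) ifelse(u >= 0, (u / tau) * exp(1 - u / tau), 0)
  out <- numeric(length(t))
  shift <- schedule$rise_time / 2
  slope <- kernel$dip_slope + slope_deviation
  for (k in seq_along(schedule$trial_onsets)) {
    amp <- slope * (schedule$trial_intensity[k] - 45)
    for (b in seq_len(schedule$bursts_per_trial)) {
      o <- schedule$trial_onsets[k] + (b - 1) * schedule$burst_period
      u <- t - o
      keep <- u >= 0 & u < 6
      if (!any(keep)) next
      v <- amp * dexp(u[keep] - kernel$dip_latency - shift,
                      kernel$dip_rise_tau, kernel$dip_decay_tau) +
        kernel$rebound_amplitude * dexp(u[keep] - kernel$rebound_delay - shift,
                                        kernel$dip_rise_tau,
                                        kernel$dip_decay_tau)
      if (phenotype == "increase") {
        h <- if (b == 1L) 1 else kernel$habituation_factor^(b - 1)
        if (h > 0)
          v <- v + kernel$onset_transient_amplitude * h *
            alpha(u[keep] - shift, kernel$onset_transient_tau)
      }
      out[keep] <- out[keep] + v
    }
  }
  out
}

# One-trial noiseless decrease-type fixture analysed without sd scaling
# (baseline sd is 0 when noise_sd = 0).
noiseless_aligned <- function(kernel, schedule, phenotype = "decrease",
                              rate = 120) {
  subj <- subject_params("s1", phenotype, noise_sd = 0,
                         drift_amplitude = 0)
  tr <- simulate_subject(subj, kernel, schedule, rate = rate)
  zscore_by_trial(tr, schedule$trial_onsets,
                  intensity = schedule$trial_intensity, normalize = FALSE)
}
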