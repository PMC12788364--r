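# Shared fixture builders. All fixtures are generated in code; no data files.

# noise-free bout parameters: the analysis stage must recover these exactly
clean_params <- function(cadence = 160, pta = 10, la = 0, rsh = 0.5,
                         duration = 60, seed = 1L) {
  bout_sim_params(cadence_spm = cadence, pta_target_g = pta, la_target = la,
                  rsh_target = rsh, duration_s = duration,
                  amp_cv = 0, timing_jitter_cv = 0, noise_sd_g = 0,
                  seed = seed)
}

noisy_params <- function(cadence = 166, pta = 10.6, la = 0.08, rsh = 0.41,
                         duration = 60, seed = 1L) {
  bout_sim_params(cadence_spm = cadence, pta_target_g = pta, la_target = la,
                  rsh_target = rsh, duration_s = duration, seed = seed)
}

# deposit a transient train into a 1 g baseline magnitude-like series
transient_train <- function(times, amplitude, duration_s, fs = 120) {
  z <- rep(1, round(duration_s * fs))
  for (t0 in times) {
    seg <- synth_impact_transient(amplitude - 1, fs)
    i0 <- round(t0 * fs) + 1
    idx <- i0:min(length(z), i0 + length(seg) - 1)
    z[idx] <- z[idx] + seg[seq_along(idx)]
  }
  z
}

# brute-force peak oracle: argmax within each window of known event times
oracle_peaks <- function(x, fs, event_times, half_window_s = 0.1) {
  vapply(event_times, function(t0) {
    idx <- max(1, round((t0 - half_window_s) * fs)):
      min(length(x), round((t0 + half_window_s) * fs) + 1)
    i <- idx[which.max(x[idx])]
    c(time_s = (i - 1) / fs, mag = x[i])
  }, numeric(2))
}

# balanced random long-format dataset for the 3-way within design
random_rm_dataset <- function(n = 10, effects = 0) {
  grid <- expand.grid(subject = sprintf("S%02d", seq_len(n)),
                      elevation_m = c(50, 1000, 2300),
                      speed_level = c("v1", "v2", "v3"),
                      surface = c("ROAD", "TRAIL"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$y <- stats::rnorm(nrow(grid)) +
    effects * (grid$speed_level == "v3") +
    stats::rnorm(n)[match(grid$subject, unique(grid$subject))]
  grid
}

# independent reference: univariate repeated-measures F tests via aov strata
aov_reference <- function(data, outcome = "y") {
  d <- data.frame(subject = factor(data$subject),
                  A = factor(data$elevation_m),
                  B = factor(data$speed_level),
                  C = factor(data$surface), y = data[[outcome]])
  fit <- summary(stats::aov(y ~ A * B * C + Error(subject / (A * B * C)),
                            data = d))
  effects <- c("A", "B", "C", "A:B", "A:C", "B:C", "A:B:C")
  out <- lapply(effects, function(e) {
    stratum <- fit[[paste0("Error: subject:", e)]][[1]]
    data.frame(effect = e, F = stratum[e, "F value"],
               p = stratum[e, "Pr(>F)"], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
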