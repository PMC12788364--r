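#' Parameters for one simulated running bout
#'
#' Bundles the programmed "ground truth" of a synthetic bout: step frequency,
#' mean tibial peak magnitude, signed lateral asymmetry, residual-shock ratio,
#' plus variability and noise settings. The downstream analysis stage is
#' expected to recover these values (exactly when all variability is zero).
#'
#' @param cadence_spm Cadence, steps per minute (both legs combined).
#' @param pta_target_g Mean tibial peak magnitude in g (bilateral mean).
#' @param la_target Signed lateral asymmetry index, `|la| < 2`
#'   (left minus right PTA over the bilateral mean).
#' @param rsh_target Residual-shock ratio (sacral over bilateral tibial peak).
#' @param duration_s Bout length in seconds; must exceed 30 s so that the
#'   two 15 s analysis margins leave a non-empty window.
#' @param fs_hz Sampling rate, default 120 Hz.
#' @param amp_cv Coefficient of variation of per-step peak amplitude.
#' @param timing_jitter_cv Coefficient of variation of inter-step intervals.
#' @param noise_sd_g SD of additive white Gaussian noise per axis, g.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG stream.
#' @return A validated list of class `bout_sim_params`.
#' @export
bout_sim_params <- function(cadence_spm, pta_target_g, la_target = 0,
                            rsh_target = 0.45, duration_s = 300,
                            fs_hz = 120, amp_cv = 0.05,
                            timing_jitter_cv = 0.03, noise_sd_g = 0.1,
                            seed = NULL) {
  p <- list(cadence_spm = cadence_spm, pta_target_g = pta_target_g,
            la_target = la_target, rsh_target = rsh_target,
            duration_s = duration_s, fs_hz = fs_hz, amp_cv = amp_cv,
            timing_jitter_cv = timing_jitter_cv, noise_sd_g = noise_sd_g,
            seed = seed)
  .check_field <- function(ok, field, why) {
    if (!isTRUE(ok)) stop(sprintf("invalid %s: %s", field, why), call. = FALSE)
  }
  .check_field(cadence_spm > 0, "cadence_spm", "must be > 0")
  .check_field(pta_target_g > 0, "pta_target_g", "must be > 0")
  .check_field(abs(la_target) < 2, "la_target",
               "|la_target| must be < 2 (algebraic bound of the asymmetry index)")
  .check_field(rsh_target > 0, "rsh_target", "must be > 0")
  .check_field(duration_s > 30, "duration_s",
               "must exceed 30 s to survive the two 15 s margins")
  .check_field(fs_hz > 16, "fs_hz",
               "must exceed twice the impact-transient centre frequency (~8 Hz)")
  .check_field(amp_cv >= 0, "amp_cv", "must be >= 0")
  .check_field(timing_jitter_cv >= 0, "timing_jitter_cv", "must be >= 0")
  .check_field(noise_sd_g >= 0, "noise_sd_g", "must be >= 0")
  structure(p, class = "bout_sim_params")
}

#' Simulate a train of alternating-leg step events
#'
#' Foot-ground impact times follow a (possibly jittered) renewal process at
#' the programmed cadence; sides strictly alternate L, R, L, R, ... With zero
#' jitter the k-th event falls at `(k - 1/2) * 60 / cadence_spm` seconds.
#'
#' @param cadence_spm Cadence, steps per minute (> 0).
#' @param duration_s Train length, seconds (> 0).
#' @param timing_jitter_cv CV of inter-step intervals (0 = perfectly regular).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param start_side First contact side, `"L"` or `"R"`.
#' @return `data.frame` with columns `time_s` (strictly increasing) and
#'   `side` (`"L"`/`"R"`).
#' @export
simulate_step_train <- function(cadence_spm, duration_s,
                                timing_jitter_cv = 0, seed = NULL,
                                start_side = "L") {
  if (cadence_spm <= 0) stop("cadence_spm must be positive", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  start_side <- match.arg(start_side, c("L", "R"))
  if (!is.null(seed)) set.seed(seed)
  base <- 60 / cadence_spm
  n_max <- ceiling(duration_s / base) + 8L
  ints <- base * (1 + timing_jitter_cv * stats::rnorm(n_max))
  ints <- pmax(ints, 0.2 * base)  # guard against negative/degenerate intervals
  times <- cumsum(ints) - ints[1L] / 2
  keep <- times < duration_s & times >= 0
  times <- times[keep]
  n <- length(times)
  sides <- rep(if (start_side == "L") c("L", "R") else c("R", "L"),
               length.out = n)
  data.frame(time_s = times, side = sides, stringsAsFactors = FALSE)
}

#' Synthesise a single impact transient
#'
#' A half-sine envelope with exponential decay, sampled on the acquisition
#' grid and rescaled so that its discrete maximum equals `amplitude_g`
#' exactly. The segment starts and ends at zero, decaying below 5% of the
#' peak by its end, and is short enough (default 0.125 s) not to overlap the
#' next step even at 240 steps/min.
#'
#' @param amplitude_g Peak value of the segment, g (> 0).
#' @param fs_hz Sampling rate, Hz.
#' @param duration_s Segment length, seconds.
#' @param decay Dimensionless exponential decay constant over the segment.
#' @return Numeric vector of g values.
#' @export
synth_impact_transient <- function(amplitude_g, fs_hz = 120,
                                   duration_s = 0.125, decay = 3) {
  if (amplitude_g <= 0) stop("amplitude_g must be positive", call. = FALSE)
  n <- max(3L, as.integer(round(duration_s * fs_hz)))
  s <- seq(0, 1, length.out = n)
  shape <- sin(pi * s) * exp(-decay * s)
  shape / max(shape) * amplitude_g
}

# Deposit transients at the sample nearest each event time onto a baseline
# vector (in place value semantics). Tails beyond the vector end are cut.
.deposit_transients <- function(z, event_times_s, amplitudes_g, fs_hz) {
  n <- length(z)
  for (i in seq_along(event_times_s)) {
    i0 <- as.integer(round(event_times_s[i] * fs_hz)) + 1L
    if (i0 > n) next
    seg <- synth_impact_transient(amplitudes_g[i], fs_hz)
    i1 <- min(n, i0 + length(seg) - 1L)
    idx <- i0:i1
    z[idx] <- z[idx] + seg[seq_along(idx)]
  }
  z
}

#' Construct a tri-axial acceleration stream
#'
#' @param t Time stamps, seconds, strictly increasing.
#' @param ax,ay,az Acceleration per axis, g (1 g = 9.80665 m/s^2).
#' @param fs_hz Nominal sampling rate.
#' @param site One of `"L_TIBIA"`, `"R_TIBIA"`, `"SACRUM"`.
#' @return Object of class `triaxial_stream`.
#' @export
triaxial_stream <- function(t, ax, ay, az, fs_hz, site) {
  site <- match.arg(site, c("L_TIBIA", "R_TIBIA", "SACRUM"))
  n <- length(t)
  if (n == 0L) stop("empty stream", call. = FALSE)
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop("channel lengths differ", call. = FALSE)
  if (n > 1L && any(diff(t) <= 0))
    stop("t must be strictly increasing", call. = FALSE)
  if (fs_hz <= 0) stop("fs_hz must be positive", call. = FALSE)
  structure(list(t = t, ax = ax, ay = ay, az = az, fs_hz = fs_hz, site = site),
            class = "triaxial_stream")
}

#' @export
print.triaxial_stream <- function(x, ...) {
  cat(sprintf("<triaxial_stream %s: %d samples @ %g Hz, %.1f s>\n",
              x$site, length(x$t), x$fs_hz, length(x$t) / x$fs_hz))
  invisible(x)
}

#' Simulate one running bout (three synchronised sensor streams)
#'
#' Generates left-tibia, right-tibia and sacrum streams sharing one time base.
#' Each tibial stream carries the impact transients of its own leg; the sacrum
#' carries every step. Per-leg mean amplitudes are the exact inversion of the
#' asymmetry index, `aL = PTA * (1 + LA/2)`, `aR = PTA * (1 - LA/2)`; the mean
#' sacral amplitude is `RSh * PTA`. A 1 g gravity baseline rides on the axial
#' (z) channel, so with zero noise the vector-magnitude peak of a step equals
#' its programmed amplitude exactly (to grid discretisation).
#'
#' @param params A [bout_sim_params()] object.
#' @return Object of class `bout_recording`: list with `streams` (named list
#'   of three [triaxial_stream()]s), `fs_hz`, `duration_s` and the programmed
#'   `params`.
#' @export
simulate_bout <- function(params) {
  if (!inherits(params, "bout_sim_params")) params <- do.call(bout_sim_params, params)
  a_mean <- c(L_TIBIA = params$pta_target_g * (1 + params$la_target / 2),
              R_TIBIA = params$pta_target_g * (1 - params$la_target / 2),
              SACRUM  = params$rsh_target * params$pta_target_g)
  if (any(a_mean <= 1))
    stop(sprintf(
      "programmed peak amplitudes must exceed the 1 g gravity baseline (got %s)",
      paste(sprintf("%s=%.2f", names(a_mean), a_mean), collapse = ", ")),
      call. = FALSE)
  if (!is.null(params$seed)) set.seed(params$seed)
  fs <- params$fs_hz
  nt <- as.integer(round(params$duration_s * fs))
  tt <- (seq_len(nt) - 1L) / fs
  train <- simulate_step_train(params$cadence_spm, params$duration_s,
                               params$timing_jitter_cv, seed = NULL)
  streams <- list()
  for (site in c("L_TIBIA", "R_TIBIA", "SACRUM")) {
    ev <- switch(site,
                 L_TIBIA = train[train$side == "L", , drop = FALSE],
                 R_TIBIA = train[train$side == "R", , drop = FALSE],
                 SACRUM  = train)
    amps <- a_mean[[site]] * (1 + params$amp_cv * stats::rnorm(nrow(ev)))
    amps <- pmax(amps, 1.05)  # keep every transient above the gravity baseline
    z <- .deposit_transients(rep(1, nt), ev$time_s, amps - 1, fs)
    if (params$noise_sd_g > 0) {
      ax <- stats::rnorm(nt, 0, params$noise_sd_g)
      ay <- stats::rnorm(nt, 0, params$noise_sd_g)
      az <- z + stats::rnorm(nt, 0, params$noise_sd_g)
    } else {
      ax <- numeric(nt); ay <- numeric(nt); az <- z
    }
    streams[[site]] <- triaxial_stream(tt, ax, ay, az, fs, site)
  }
  structure(list(streams = streams, fs_hz = fs,
                 duration_s = params$duration_s, params = params),
            class = "bout_recording")
}

#' @export
print.bout_recording <- function(x, ...) {
  cat(sprintf(
    "<bout_recording: %.0f s @ %g Hz; programmed CAD %.1f spm, PTA %.2f g, LA %+.3f, RSh %.3f>\n",
    x$duration_s, x$fs_hz, x$params$cadence_spm, x$params$pta_target_g,
    x$params$la_target, x$params$rsh_target))
  invisible(x)
}
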