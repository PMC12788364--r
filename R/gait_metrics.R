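#' Euclidean vector magnitude of a tri-axial stream
#'
#' @param stream A [triaxial_stream()].
#' @return Numeric vector `sqrt(ax^2 + ay^2 + az^2)`, same length as the
#'   input, in g.
#' @export
vector_magnitude <- function(stream) {
  stopifnot(inherits(stream, "triaxial_stream"))
  if (length(stream$t) == 0L) stop("empty stream", call. = FALSE)
  sqrt(stream$ax^2 + stream$ay^2 + stream$az^2)
}

#' Peak-detection policy
#'
#' The detection threshold is adaptive: median of the magnitude series plus
#' `k_mad` times its MAD, which tracks the noise floor around the 1 g gravity
#' baseline regardless of noise scale. Minimum inter-peak distances reflect
#' physiology: one stride per leg at a tibial site (0.35 s allows per-leg
#' rates up to ~171 steps/min/leg), one step at the sacrum (0.20 s allows up
#' to 300 steps/min combined).
#'
#' @param k_mad Threshold multiplier on the MAD.
#' @param min_dist_tibia_s Minimum peak separation for tibial sites, s.
#' @param min_dist_sacrum_s Minimum peak separation for the sacrum, s.
#' @return List of class `peak_policy`.
#' @export
peak_policy <- function(k_mad = 4, min_dist_tibia_s = 0.35,
                        min_dist_sacrum_s = 0.20) {
  if (k_mad <= 0 || min_dist_tibia_s <= 0 || min_dist_sacrum_s <= 0)
    stop("invalid peak policy: all parameters must be positive", call. = FALSE)
  structure(list(k_mad = k_mad, min_dist_tibia_s = min_dist_tibia_s,
                 min_dist_sacrum_s = min_dist_sacrum_s),
            class = "peak_policy")
}

#' Detect impact peaks in an acceleration-magnitude series
#'
#' Local maxima above the adaptive threshold, pruned so that no two retained
#' events lie closer than the site's minimum distance; when two candidates
#' conflict the larger magnitude wins (ties go to the earlier event). A flat
#' or entirely sub-threshold series yields zero events.
#'
#' @param magnitude_series Numeric vector of magnitudes, g.
#' @param fs_hz Sampling rate, Hz.
#' @param site Sensor site (`"L_TIBIA"`, `"R_TIBIA"`, `"SACRUM"`).
#' @param policy A [peak_policy()].
#' @return `data.frame` with columns `time_s`, `site`, `peak_magnitude_g`,
#'   ordered by time.
#' @export
detect_impact_peaks <- function(magnitude_series, fs_hz, site,
                                policy = peak_policy()) {
  if (!inherits(policy, "peak_policy")) stop("invalid policy", call. = FALSE)
  site <- match.arg(site, c("L_TIBIA", "R_TIBIA", "SACRUM"))
  x <- magnitude_series
  n <- length(x)
  if (n <= 2L) stop("magnitude series too short", call. = FALSE)
  if (fs_hz <= 0) stop("fs_hz must be positive", call. = FALSE)
  thr <- stats::median(x) + policy$k_mad * stats::mad(x)
  mid <- 2:(n - 1L)
  cand <- mid[x[mid] > x[mid - 1L] & x[mid] >= x[mid + 1L] & x[mid] > thr]
  empty <- data.frame(time_s = numeric(0), site = character(0),
                      peak_magnitude_g = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(cand) == 0L) return(empty)
  min_dist <- if (site == "SACRUM") policy$min_dist_sacrum_s else
    policy$min_dist_tibia_s
  min_gap <- min_dist * fs_hz
  # greedy by magnitude (ties -> earlier index), then enforce separation
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L || min(abs(kept - i)) >= min_gap)
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(time_s = (kept - 1L) / fs_hz, site = site,
             peak_magnitude_g = x[kept], stringsAsFactors = FALSE)
}

#' Discard events inside the initialisation/finalisation margins
#'
#' Gait metrics are averaged over the steady portion of a bout, discarding a
#' margin (default 15 s) at each end.
#'
#' @param events Event `data.frame` with a `time_s` column.
#' @param bout_duration_s Total bout duration, s; must exceed `2 * margin_s`.
#' @param margin_s Margin length at each end, s.
#' @return The filtered events. The effective analysis duration is
#'   `bout_duration_s - 2 * margin_s`.
#' @export
trim_margins <- function(events, bout_duration_s, margin_s = 15) {
  if (bout_duration_s <= 2 * margin_s)
    stop("bout too short for margins", call. = FALSE)
  events[events$time_s >= margin_s &
           events$time_s <= bout_duration_s - margin_s, , drop = FALSE]
}

#' Mean peak acceleration over a bout
#'
#' @param events Event `data.frame` with `peak_magnitude_g`.
#' @return Arithmetic mean of the per-step peak magnitudes, g.
#' @export
mean_peak_acceleration <- function(events) {
  if (nrow(events) == 0L) stop("no steps detected", call. = FALSE)
  mean(events$peak_magnitude_g)
}

#' Cadence from combined left and right impact events
#'
#' @param events_left,events_right Trimmed event tables for the two tibiae.
#' @param effective_duration_s Analysis window length (bout minus margins), s.
#' @return Cadence in steps per minute.
#' @export
compute_cadence <- function(events_left, events_right, effective_duration_s) {
  if (effective_duration_s <= 0)
    stop("effective_duration_s must be positive", call. = FALSE)
  n <- nrow(events_left) + nrow(events_right)
  if (n == 0L) stop("no steps detected", call. = FALSE)
  n / effective_duration_s * 60
}

#' Lateral asymmetry index of peak tibial acceleration
#'
#' `LA = (aL - aR) / ((aL + aR) / 2)`; positive when the left leg loads
#' harder. `aLA = |LA|` is used for group means so that opposite-signed
#' individual asymmetries cannot cancel. `LA` is algebraically confined to
#' (-2, 2) for positive inputs.
#'
#' @param a_L,a_R Mean peak tibial acceleration of the left/right shank, g.
#' @return List with `la` (signed) and `ala` (absolute).
#' @export
lateral_asymmetry <- function(a_L, a_R) {
  if (any(a_L <= 0) || any(a_R <= 0))
    stop("tibial peak accelerations must be positive", call. = FALSE)
  la <- (a_L - a_R) / ((a_L + a_R) / 2)
  list(la = la, ala = abs(la))
}

#' Residual shock at the pelvis
#'
#' `RSh = aSac / ((aL + aR) / 2)`: the fraction of the mean tibial impact
#' peak still seen at the sacrum. `1 - RSh` is the shock attenuation.
#'
#' @param a_Sac Mean sacral peak acceleration, g.
#' @param a_L,a_R Mean peak tibial accelerations, g.
#' @return Residual-shock ratio (dimensionless).
#' @export
residual_shock <- function(a_Sac, a_L, a_R) {
  if (any(a_Sac <= 0) || any(a_L <= 0) || any(a_R <= 0))
    stop("peak accelerations must be positive", call. = FALSE)
  a_Sac / ((a_L + a_R) / 2)
}

#' Full per-bout gait analysis
#'
#' Runs the complete post-processing chain on one recording: vector
#' magnitude, impact-peak detection per site, margin trimming, then cadence,
#' per-leg and sacral mean peaks, lateral asymmetry and residual shock.
#' The sacral event count serves as a cross-check on cadence; a warning is
#' issued when it deviates from the tibial union count by more than 2%.
#'
#' @param recording A [simulate_bout()] result or any `bout_recording` with
#'   `L_TIBIA`, `R_TIBIA` and `SACRUM` streams.
#' @param policy A [peak_policy()].
#' @param margin_s Initialisation/finalisation margin, s.
#' @return Object of class `bout_metrics` (also a one-row list convertible
#'   with [as.data.frame()]): `cad_spm`, `pta_left_g`, `pta_right_g`,
#'   `pta_mean_g`, `sacral_peak_g`, `la`, `ala`, `rsh`, `n_steps`,
#'   `effective_duration_s`.
#' @export
analyse_bout <- function(recording, policy = peak_policy(), margin_s = 15) {
  stopifnot(inherits(recording, "bout_recording") || is.list(recording))
  streams <- recording$streams
  for (site in c("L_TIBIA", "R_TIBIA", "SACRUM"))
    if (is.null(streams[[site]]))
      stop(sprintf("recording is missing the %s stream", site), call. = FALSE)
  dur <- recording$duration_s
  if (dur <= 2 * margin_s) stop("bout too short for margins", call. = FALSE)
  ev <- lapply(streams, function(s) {
    e <- detect_impact_peaks(vector_magnitude(s), s$fs_hz, s$site, policy)
    trim_margins(e, dur, margin_s)
  })
  eff <- dur - 2 * margin_s
  for (site in c("L_TIBIA", "R_TIBIA"))
    if (nrow(ev[[site]]) == 0L)
      stop(sprintf("no steps detected at %s", site), call. = FALSE)
  a_L <- mean_peak_acceleration(ev$L_TIBIA)
  a_R <- mean_peak_acceleration(ev$R_TIBIA)
  if (nrow(ev$SACRUM) == 0L)
    stop("no steps detected at SACRUM", call. = FALSE)
  a_S <- mean_peak_acceleration(ev$SACRUM)
  cad <- compute_cadence(ev$L_TIBIA, ev$R_TIBIA, eff)
  n_tib <- nrow(ev$L_TIBIA) + nrow(ev$R_TIBIA)
  n_sac <- nrow(ev$SACRUM)
  # one event of slack absorbs window-edge quantisation on short bouts
  if (abs(n_sac - n_tib) > max(0.02 * n_tib, 1))
    warning(sprintf(
      "sacral event count (%d) deviates from tibial union (%d) by > 2%%",
      n_sac, n_tib), call. = FALSE)
  asym <- lateral_asymmetry(a_L, a_R)
  structure(list(
    cad_spm = cad, pta_left_g = a_L, pta_right_g = a_R,
    pta_mean_g = (a_L + a_R) / 2, sacral_peak_g = a_S,
    la = asym$la, ala = asym$ala,
    rsh = residual_shock(a_S, a_L, a_R),
    n_steps = n_tib, effective_duration_s = eff
  ), class = "bout_metrics")
}

#' @export
print.bout_metrics <- function(x, ...) {
  cat(sprintf(
    "<bout_metrics: CAD %.1f spm, PTA %.2f g (L %.2f / R %.2f), aLA %.1f%%, RSh %.1f%%, %d steps / %.0f s>\n",
    x$cad_spm, x$pta_mean_g, x$pta_left_g, x$pta_right_g,
    100 * x$ala, 100 * x$rsh, x$n_steps, x$effective_duration_s))
  invisible(x)
}

#' @export
as.data.frame.bout_metrics <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}
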