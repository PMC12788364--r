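# Cohort-level synthesis: a calibration table states the target mean +- SD of
# each gait metric in every design cell (3 elevations x 3 speeds x 2
# surfaces); subject profiles carry stable individual traits (threshold
# speeds, standardised random effects, a fixed asymmetry sign).

.ELEVATIONS_M <- c(50, 1000, 2300)
.SPEED_LEVELS <- c("v1", "v2", "v3")
.SURFACES <- c("ROAD", "TRAIL")

#' Default cohort calibration (18 design cells)
#'
#' Target means and between-subject SDs for cadence, peak tibial
#' acceleration, absolute lateral asymmetry and residual shock in every
#' (elevation, speed, surface) cell. Cell values combine the per-speed
#' marginal distributions with additive per-elevation offsets for cadence
#' and PTA; asymmetry and residual shock carry no elevation structure and no
#' metric carries a surface mean shift (surfaces differ only in signal
#' variability, see [simulate_cohort()]). The cadence marginal at 1000 m is
#' linearly interpolated between the 50 m and 2300 m values (166.8 and
#' 164.6 spm), as only those two are tabulated.
#'
#' @return `data.frame` of class `cohort_calibration` with 18 rows and
#'   columns `elevation_m`, `speed_level`, `surface`, and `<metric>_mean` /
#'   `<metric>_sd` for `cad` (spm), `pta` (g), `ala` and `rsh` (fractions).
#' @export
default_calibration <- function() {
  speed <- data.frame(
    speed_level = .SPEED_LEVELS,
    cad_mean = c(160, 166, 172), cad_sd = c(7, 9, 9),
    pta_mean = c(7.8, 10.6, 12.5), pta_sd = c(1.6, 1.8, 1.6),
    ala_mean = c(0.093, 0.082, 0.069), ala_sd = c(0.046, 0.027, 0.023),
    rsh_mean = c(0.501, 0.412, 0.362), rsh_sd = c(0.080, 0.074, 0.076),
    stringsAsFactors = FALSE)
  cad_elev <- c(166.8, 166.8 + (164.6 - 166.8) * (1000 - 50) / (2300 - 50),
                164.6)
  pta_elev <- c(10.7, 10.2, 10.1)
  elev <- data.frame(
    elevation_m = .ELEVATIONS_M,
    cad_offset = cad_elev - mean(cad_elev),
    pta_offset = pta_elev - mean(pta_elev))
  cells <- expand.grid(elevation_m = .ELEVATIONS_M,
                       speed_level = .SPEED_LEVELS,
                       surface = .SURFACES,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- merge(cells, speed, by = "speed_level")
  cells <- merge(cells, elev, by = "elevation_m")
  cells$cad_mean <- cells$cad_mean + cells$cad_offset
  cells$pta_mean <- cells$pta_mean + cells$pta_offset
  cells$cad_offset <- cells$pta_offset <- NULL
  cells <- cells[order(cells$elevation_m, cells$speed_level, cells$surface), ]
  rownames(cells) <- NULL
  class(cells) <- c("cohort_calibration", "data.frame")
  cells
}

#' Validate a cohort calibration table
#'
#' @param calibration A calibration `data.frame` (see [default_calibration()]).
#' @return The calibration, invisibly, after checking that all 18 design
#'   cells are present exactly once and all SDs are non-negative.
#' @export
validate_calibration <- function(calibration) {
  need <- expand.grid(elevation_m = .ELEVATIONS_M,
                      speed_level = .SPEED_LEVELS, surface = .SURFACES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$elevation_m, d$speed_level, d$surface, sep = "/")
  missing <- setdiff(key(need), key(calibration))
  if (length(missing) > 0L)
    stop("calibration is missing cells: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(key(calibration)))
    stop("calibration has duplicated cells", call. = FALSE)
  sds <- unlist(calibration[grep("_sd$", names(calibration))])
  if (any(sds < 0)) stop("calibration SDs must be >= 0", call. = FALSE)
  invisible(calibration)
}

#' Generate subject profiles
#'
#' Draws ventilatory-threshold speeds around the cohort distribution
#' (vVT1 10.4 +- 0.7 km/h, vVT2 = vVT1 + 4.6 +- 1.2 km/h) and stable
#' per-subject random effects for each gait metric. The random effects are
#' standardised to sample mean 0 and SD 1, so that programmed cohort means
#' and SDs equal the calibration targets exactly at any cohort size
#' (a calibrated-cohort design; see the methods vignette). Each subject also
#' receives a fixed asymmetry sign: lateral asymmetry is treated as a stable
#' individual trait.
#'
#' @param n Number of subjects (>= 2).
#' @param seed Optional integer seed.
#' @return `data.frame` of class `subject_profiles` with columns
#'   `subject_id`, `vVT1_kmh`, `vVT2_kmh`, standardised effects `z_cad`,
#'   `z_pta`, `z_ala`, `z_rsh`, and `la_sign`.
#' @export
make_subject_profiles <- function(n, seed = NULL) {
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  vVT1 <- stats::rnorm(n, 10.4, 0.7)
  vVT2 <- vVT1 + pmax(stats::rnorm(n, 4.6, 1.2), 0.5)
  std <- function(z) as.numeric(scale(z))
  prof <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    vVT1_kmh = vVT1, vVT2_kmh = vVT2,
    z_cad = std(stats::rnorm(n)), z_pta = std(stats::rnorm(n)),
    z_ala = std(stats::rnorm(n)), z_rsh = std(stats::rnorm(n)),
    la_sign = sample(c(-1, 1), n, replace = TRUE),
    stringsAsFactors = FALSE)
  class(prof) <- c("subject_profiles", "data.frame")
  prof
}

#' Simulate a full crossover cohort
#'
#' Every subject runs all 18 cells (3 elevations x 3 speeds x 2 surfaces).
#' Per-cell programmed values are `mean + z_subject * sd` from the
#' calibration; lateral asymmetry is programmed as the subject's fixed sign
#' times the (clamped non-negative) absolute asymmetry. TRAIL bouts receive
#' a relative increment (default +50%) on amplitude CV and timing jitter
#' instead of any mean shift. The design table records subject, cell,
#' prescribed (altitude-adjusted) speed, the programmed parameters and the
#' per-bout RNG seed, so any bout can be regenerated in isolation.
#'
#' @param profiles A [make_subject_profiles()] table (or an integer: number
#'   of subjects to generate).
#' @param calibration Calibration table; default [default_calibration()].
#' @param seed Integer seed governing the whole cohort.
#' @param duration_s Bout duration, seconds (study bouts last >= 5 min).
#' @param fs_hz Sampling rate, Hz.
#' @param amp_cv,timing_jitter_cv,noise_sd_g Baseline variability settings
#'   (ROAD); see [bout_sim_params()].
#' @param trail_factor Relative increment of `amp_cv` and `timing_jitter_cv`
#'   on TRAIL.
#' @param handler Optional `function(recording, design_row)`; when given,
#'   each bout is passed to it right after generation and **not** retained
#'   (constant-memory streaming), and the handler results are returned in
#'   place of the recordings.
#' @param verbose Emit one log line per bout.
#' @return List of class `cohort_simulation` with `design` (one row per
#'   bout) and `bouts` (list of [simulate_bout()] recordings, or handler
#'   results).
#' @export
simulate_cohort <- function(profiles, calibration = default_calibration(),
                            seed = 1L, duration_s = 300, fs_hz = 120,
                            amp_cv = 0.05, timing_jitter_cv = 0.03,
                            noise_sd_g = 0.1, trail_factor = 0.5,
                            handler = NULL, verbose = FALSE) {
  if (is.numeric(profiles) && length(profiles) == 1L)
    profiles <- make_subject_profiles(profiles)
  if (nrow(profiles) < 2L) stop("need at least 2 subjects", call. = FALSE)
  validate_calibration(calibration)
  set.seed(seed)
  design <- merge(data.frame(subject = profiles$subject_id,
                             stringsAsFactors = FALSE),
                  as.data.frame(calibration), by = NULL)
  design <- design[order(design$subject, design$elevation_m,
                         design$speed_level, design$surface), ]
  rownames(design) <- NULL
  pi <- match(design$subject, profiles$subject_id)
  zones <- Map(speed_zones, profiles$vVT1_kmh[pi], profiles$vVT2_kmh[pi])
  v_level <- vapply(seq_len(nrow(design)), function(i)
    zones[[i]][[paste0(design$speed_level[i], "_kmh")]], numeric(1))
  design$speed_prescribed_kmh <- adjust_speed(v_level, design$elevation_m)
  design$cad_prog <- design$cad_mean + profiles$z_cad[pi] * design$cad_sd
  design$pta_prog <- design$pta_mean + profiles$z_pta[pi] * design$pta_sd
  ala_prog <- pmax(design$ala_mean + profiles$z_ala[pi] * design$ala_sd, 0.002)
  design$la_prog <- profiles$la_sign[pi] * ala_prog
  design$rsh_prog <- pmax(design$rsh_mean + profiles$z_rsh[pi] * design$rsh_sd,
                          0.05)
  is_trail <- design$surface == "TRAIL"
  design$amp_cv <- amp_cv * (1 + trail_factor * is_trail)
  design$timing_jitter_cv <- timing_jitter_cv * (1 + trail_factor * is_trail)
  design$noise_sd_g <- noise_sd_g
  design$bout_seed <- sample.int(.Machine$integer.max, nrow(design))
  design <- design[, c("subject", "elevation_m", "speed_level", "surface",
                       "speed_prescribed_kmh", "cad_prog", "pta_prog",
                       "la_prog", "rsh_prog", "amp_cv", "timing_jitter_cv",
                       "noise_sd_g", "bout_seed")]

  bouts <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    rec <- simulate_bout(bout_sim_params(
      cadence_spm = row$cad_prog, pta_target_g = row$pta_prog,
      la_target = row$la_prog, rsh_target = row$rsh_prog,
      duration_s = duration_s, fs_hz = fs_hz, amp_cv = row$amp_cv,
      timing_jitter_cv = row$timing_jitter_cv, noise_sd_g = row$noise_sd_g,
      seed = row$bout_seed))
    if (verbose)
      message(sprintf("bout %s %dm %s %s: CAD %.1f, PTA %.2f g",
                      row$subject, row$elevation_m, row$speed_level,
                      row$surface, row$cad_prog, row$pta_prog))
    bouts[[i]] <- if (is.null(handler)) rec else handler(rec, row)
  }
  structure(list(design = design, bouts = bouts, profiles = profiles),
            class = "cohort_simulation")
}
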