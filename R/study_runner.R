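#' Study configuration
#'
#' Bundles every knob of a full synthetic replication run: cohort size,
#' seed, bout geometry, signal variability, and which statistics to emit.
#'
#' @param n_subjects Number of subjects (>= 2; statistics need >= 3).
#' @param seed Integer seed; a fixed seed makes the whole run reproducible.
#' @param duration_s Bout duration in seconds.
#' @param fs_hz Sampling rate, Hz.
#' @param amp_cv,timing_jitter_cv,noise_sd_g Baseline (ROAD) variability.
#' @param trail_factor Relative variability increment on TRAIL.
#' @param run_stats Run the three-way rmANOVA and post hoc stage.
#' @param out_dir Output directory, or `NULL` for no file output.
#' @param verbose Log one line per bout.
#' @return List of class `study_config`.
#' @export
study_config <- function(n_subjects = 10, seed = 1L, duration_s = 300,
                         fs_hz = 120, amp_cv = 0.05, timing_jitter_cv = 0.03,
                         noise_sd_g = 0.1, trail_factor = 0.5,
                         run_stats = TRUE, out_dir = NULL, verbose = FALSE) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (duration_s <= 30) stop("duration_s must exceed 30 s", call. = FALSE)
  structure(as.list(environment()), class = "study_config")
}

#' Analyse a whole cohort into a metrics table
#'
#' Streams the cohort bout by bout (generate, analyse, discard) so memory
#' stays constant, and returns one metrics row per bout joined with its
#' design cell.
#'
#' @param config A [study_config()].
#' @param calibration Calibration table.
#' @return List with `metrics` (`data.frame`, one row per bout) and
#'   `design`.
#' @export
cohort_metrics <- function(config, calibration = default_calibration()) {
  stopifnot(inherits(config, "study_config"))
  profiles <- make_subject_profiles(config$n_subjects, seed = config$seed)
  sim <- simulate_cohort(
    profiles, calibration, seed = config$seed + 1L,
    duration_s = config$duration_s, fs_hz = config$fs_hz,
    amp_cv = config$amp_cv, timing_jitter_cv = config$timing_jitter_cv,
    noise_sd_g = config$noise_sd_g, trail_factor = config$trail_factor,
    verbose = config$verbose,
    handler = function(rec, row) {
      m <- analyse_bout(rec)
      if (config$verbose)
        message(sprintf("analysed %s %dm %s %s: %d steps",
                        row$subject, row$elevation_m, row$speed_level,
                        row$surface, m$n_steps))
      as.data.frame(m)
    })
  metrics <- cbind(
    sim$design[, c("subject", "elevation_m", "speed_level", "surface",
                   "speed_prescribed_kmh")],
    do.call(rbind, sim$bouts))
  rownames(metrics) <- NULL
  list(metrics = metrics, design = sim$design, profiles = profiles)
}

# SD convention for summaries: a single observation has SD 0, not NA
.sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)

#' Per-cell summary of a metrics table
#'
#' @param metrics Metrics table (one row per bout) with the design columns
#'   and the gait metrics.
#' @return `data.frame` of class `cell_summary`: one row per
#'   (elevation, speed, surface) cell with mean and SD of `cad_spm`,
#'   `pta_mean_g`, `ala` and `rsh`.
#' @export
summarise_cells <- function(metrics) {
  if (nrow(metrics) == 0L) stop("empty metrics table", call. = FALSE)
  key <- interaction(metrics$elevation_m, metrics$speed_level,
                     metrics$surface, drop = TRUE, sep = "/")
  first <- !duplicated(key)
  out <- data.frame(
    elevation_m = metrics$elevation_m[first],
    speed_level = metrics$speed_level[first],
    surface = metrics$surface[first], stringsAsFactors = FALSE)
  out <- out[order(out$elevation_m, out$speed_level, out$surface), ]
  okey <- paste(out$elevation_m, out$speed_level, out$surface, sep = "/")
  for (v in c("cad_spm", "pta_mean_g", "ala", "rsh")) {
    mu <- tapply(metrics[[v]], key, mean)
    sd_ <- tapply(metrics[[v]], key, .sd0)
    out[[paste0(v, "_mean")]] <- as.numeric(mu[match(okey, names(mu))])
    out[[paste0(v, "_sd")]] <- as.numeric(sd_[match(okey, names(sd_))])
  }
  rownames(out) <- NULL
  class(out) <- c("cell_summary", "data.frame")
  out
}

#' Marginal means and SDs of a metrics table along one factor
#'
#' @param metrics Metrics table.
#' @param factor_name One of the design factor columns.
#' @return `data.frame` with one row per factor level.
#' @export
summarise_marginal <- function(metrics, factor_name) {
  f <- factor(metrics[[factor_name]])
  lev <- if (is.numeric(metrics[[factor_name]])) as.numeric(levels(f)) else
    levels(f)
  out <- data.frame(level = lev, stringsAsFactors = FALSE)
  names(out) <- factor_name
  for (v in c("cad_spm", "pta_mean_g", "ala", "rsh")) {
    out[[paste0(v, "_mean")]] <- as.numeric(tapply(metrics[[v]], f, mean))
    out[[paste0(v, "_sd")]] <- as.numeric(tapply(metrics[[v]], f, .sd0))
  }
  out
}

#' Run the full synthetic study
#'
#' Generates the cohort, analyses every bout, summarises the 18 design
#' cells, and (optionally) runs the three-way repeated-measures ANOVA and
#' the per-speed post hoc comparisons for each gait metric. When
#' `config$out_dir` is set, writes `design.csv`, `metrics.csv`,
#' `cell_summary.csv`, `effects_<metric>.csv`, `posthoc_<metric>.csv` and a
#' plain-text `report.txt`. Identical configurations (including seed)
#' produce byte-identical CSV output.
#'
#' @param config A [study_config()].
#' @param calibration Calibration table.
#' @return List of class `study_result` with `metrics`, `design`,
#'   `cell_summary`, `marginals`, and (if requested and feasible) `anova`
#'   and `posthoc` per metric.
#' @export
run_study <- function(config = study_config(),
                      calibration = default_calibration()) {
  cm <- cohort_metrics(config, calibration)
  metrics <- cm$metrics
  cells <- summarise_cells(metrics)
  marginals <- lapply(stats::setNames(nm = c("elevation_m", "speed_level",
                                             "surface")),
                      function(f) summarise_marginal(metrics, f))
  outcomes <- c("cad_spm", "pta_mean_g", "ala", "rsh")
  res <- structure(list(config = config, metrics = metrics,
                        design = cm$design, cell_summary = cells,
                        marginals = marginals, anova = NULL, posthoc = NULL),
                   class = "study_result")
  # metrics artifacts are written before the statistics stage so a stats
  # failure (e.g. too few subjects) never discards the analysed bouts
  if (!is.null(config$out_dir)) .write_study_base(res, config$out_dir)
  if (isTRUE(config$run_stats)) {
    if (config$n_subjects < 3L)
      stop("insufficient subjects for rmANOVA: need >= 3 (bout metrics were still computed and written)",
           call. = FALSE)
    res$anova <- lapply(stats::setNames(nm = outcomes), function(y)
      rm_anova_3way(metrics, y))
    res$posthoc <- lapply(stats::setNames(nm = outcomes), function(y)
      posthoc_pairwise(metrics, y, "speed_level"))
  }
  if (!is.null(config$out_dir)) .write_study_stats(res, config$out_dir)
  res
}

.write_study_base <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gaitload_csv(res$design, file.path(dir, "design.csv"))
  write_gaitload_csv(res$metrics, file.path(dir, "metrics.csv"))
  write_gaitload_csv(res$cell_summary, file.path(dir, "cell_summary.csv"))
  invisible(dir)
}

.write_study_stats <- function(res, dir) {
  if (!is.null(res$anova)) {
    for (y in names(res$anova)) {
      write_gaitload_csv(as.data.frame(res$anova[[y]]),
                         file.path(dir, sprintf("effects_%s.csv", y)))
      write_gaitload_csv(res$posthoc[[y]],
                         file.path(dir, sprintf("posthoc_%s.csv", y)))
    }
  }
  writeLines(.study_report(res), file.path(dir, "report.txt"))
  invisible(dir)
}

.study_report <- function(res) {
  sp <- res$marginals$speed_level
  el <- res$marginals$elevation_m
  lines <- c(
    sprintf("gaitload study report (%d subjects, seed %d)",
            as.integer(res$config$n_subjects), as.integer(res$config$seed)),
    "",
    "Speed-level marginals (mean +- SD):",
    sprintf("  %s: CAD %.1f +- %.1f spm, PTA %.1f +- %.1f g, aLA %.1f +- %.1f %%, RSh %.1f +- %.1f %%",
            sp$speed_level, sp$cad_spm_mean, sp$cad_spm_sd,
            sp$pta_mean_g_mean, sp$pta_mean_g_sd,
            100 * sp$ala_mean, 100 * sp$ala_sd,
            100 * sp$rsh_mean, 100 * sp$rsh_sd),
    "",
    "Elevation marginals (mean +- SD):",
    sprintf("  %4.0f m: CAD %.1f +- %.1f spm, PTA %.1f +- %.1f g",
            el$elevation_m, el$cad_spm_mean, el$cad_spm_sd,
            el$pta_mean_g_mean, el$pta_mean_g_sd))
  if (!is.null(res$anova)) {
    for (y in names(res$anova)) {
      a <- res$anova[[y]]
      lines <- c(lines, "", sprintf("rmANOVA for %s:", y),
                 sprintf("  %-40s F(%g, %g) = %8.3f, p = %.4g, eta_p^2 = %.3f (%s)",
                         a$effect, a$df_num, a$df_den, a$F, a$p,
                         a$partial_eta_sq, a$rating))
    }
  }
  lines
}

#' @export
print.study_result <- function(x, ...) {
  cat(paste(.study_report(x), collapse = "\n"), "\n")
  invisible(x)
}
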