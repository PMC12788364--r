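# Plain-text interchange formats. Time series are CSV (t_s, ax_g, ay_g,
# az_g), one file per sensor site, with a JSON sidecar of the programmed
# bout parameters; tabular outputs are CSV with a schema-version header
# comment so diffs stay bit-stable across package versions.

.SCHEMA_HEADER <- "# gaitload csv schema 1"

#' Write a table as schema-versioned CSV
#'
#' @param df `data.frame` to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaitload_csv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.SCHEMA_HEADER, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a schema-versioned CSV table
#'
#' @param path Input path.
#' @return `data.frame`.
#' @export
read_gaitload_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write one bout recording to a directory
#'
#' Creates `<site>.csv` (columns `t_s`, `ax_g`, `ay_g`, `az_g`) for each of
#' the three sensor sites plus `params.json` with the programmed parameters.
#'
#' @param recording A `bout_recording`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bout <- function(recording, dir) {
  stopifnot(inherits(recording, "bout_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (site in names(recording$streams)) {
    s <- recording$streams[[site]]
    write_gaitload_csv(
      data.frame(t_s = s$t, ax_g = s$ax, ay_g = s$ay, az_g = s$az),
      file.path(dir, paste0(tolower(site), ".csv")))
  }
  meta <- recording$params
  meta$fs_hz <- recording$fs_hz
  meta$duration_s <- recording$duration_s
  jsonlite::write_json(unclass(meta), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a bout recording from a directory written by [write_bout()]
#'
#' @param dir Directory containing `l_tibia.csv`, `r_tibia.csv`,
#'   `sacrum.csv` and optionally `params.json`.
#' @return A `bout_recording`.
#' @export
read_bout <- function(dir) {
  sites <- c("L_TIBIA", "R_TIBIA", "SACRUM")
  streams <- list()
  meta <- NULL
  pj <- file.path(dir, "params.json")
  if (file.exists(pj)) meta <- jsonlite::read_json(pj, simplifyVector = TRUE)
  for (site in sites) {
    path <- file.path(dir, paste0(tolower(site), ".csv"))
    if (!file.exists(path))
      stop(sprintf("missing %s stream file: %s", site, path), call. = FALSE)
    d <- read_gaitload_csv(path)
    fs <- if (!is.null(meta$fs_hz)) meta$fs_hz else
      1 / stats::median(diff(d$t_s))
    streams[[site]] <- triaxial_stream(d$t_s, d$ax_g, d$ay_g, d$az_g, fs, site)
  }
  dur <- if (!is.null(meta$duration_s)) meta$duration_s else
    max(streams$L_TIBIA$t) + 1 / streams$L_TIBIA$fs_hz
  structure(list(streams = streams, fs_hz = streams$L_TIBIA$fs_hz,
                 duration_s = dur, params = meta),
            class = "bout_recording")
}

#' Read a study configuration from a JSON file
#'
#' Recognised keys mirror the arguments of [study_config()]; unknown keys
#' are rejected to catch typos.
#'
#' @param path JSON file path.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L)
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(study_config, raw)
}
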