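# Delimited-text readers/writers with JSON sidecars. All tabular artifacts
# are comma-separated UTF-8 with a header row; round trips reproduce values
# to full double precision.

# fail with row/column coordinates when a cell is not numeric
check_numeric_cols <- function(df, cols, path) {
  for (nm in cols) {
    v <- df[[nm]]
    suppressWarnings(num <- as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "NA")
    if (length(bad) > 0) {
      stop(sprintf("parse error in %s: non-numeric value '%s' at row %d, column '%s'",
                   path, v[bad[1]], bad[1], nm), call. = FALSE)
    }
    df[[nm]] <- num
  }
  df
}

read_delim_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0) {
    stop(sprintf("empty file: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0) stop(sprintf("empty series in %s", path), call. = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("schema mismatch in %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write / read an IMU series as delimited text
#'
#' Columns: `time_s`, `hip_flex_deg`, `hip_angvel_degs`, and optionally
#' `torso_yaw_deg`.
#'
#' @param series an [imu_series()].
#' @param path output file.
#' @return `write_imu_series` the path invisibly; `read_imu_series` an
#'   `imu_series`.
#' @export
write_imu_series <- function(series, path) {
  df <- data.frame(time_s = series$t, hip_flex_deg = series$hip_flexion,
                   hip_angvel_degs = series$hip_angvel)
  if (!is.null(series$torso_yaw)) df$torso_yaw_deg <- series$torso_yaw
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_imu_series
#' @param nominal_rate sampling rate to attach on read, Hz.
#' @export
read_imu_series <- function(path, nominal_rate = 333) {
  df <- read_delim_checked(path, c("time_s", "hip_flex_deg", "hip_angvel_degs"))
  cols <- intersect(c("time_s", "hip_flex_deg", "hip_angvel_degs",
                      "torso_yaw_deg"), names(df))
  df <- check_numeric_cols(df, cols, path)
  imu_series(df$time_s, df$hip_flex_deg, df$hip_angvel_degs,
             if ("torso_yaw_deg" %in% names(df)) df$torso_yaw_deg else NULL,
             nominal_rate)
}

#' Write / read a gait-event table as delimited text
#'
#' Columns: `leg` (L/R), `event_type` (HS/TO), `time_s`.
#'
#' @param events a [gait_events()] table.
#' @param path file path.
#' @export
write_gait_events <- function(events, path) {
  df <- data.frame(leg = events$leg, event_type = events$event,
                   time_s = format(events$time_s, digits = 17, trim = TRUE,
                                   scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gait_events
#' @export
read_gait_events <- function(path) {
  df <- read_delim_checked(path, c("leg", "event_type", "time_s"))
  df <- check_numeric_cols(df, "time_s", path)
  gait_events(df$leg, df$event_type, df$time_s)
}

#' Write a phase series as delimited text
#'
#' Columns: `time_s`, `phase_rad`, `segment` (warm-up rows carry `NA`).
#'
#' @param ps a `phase_series`.
#' @param path file path.
#' @export
write_phase_series <- function(ps, path) {
  df <- data.frame(time_s = ps$t, phase_rad = ps$phase, segment = ps$segment)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phase_series
#' @export
read_phase_series <- function(path) {
  df <- read_delim_checked(path, c("time_s", "phase_rad", "segment"))
  df <- check_numeric_cols(df, c("time_s", "phase_rad", "segment"), path)
  structure(list(t = df$time_s, phase = df$phase_rad,
                 segment = as.integer(df$segment)),
            class = "phase_series")
}

#' Write / read a waveform matrix with a JSON sidecar
#'
#' The matrix (strides x nodes) is written as delimited text; labels,
#' flags, dimensions and provenance go into `<path>.json`.
#'
#' @param mat numeric matrix, rows = strides, columns = nodes.
#' @param path file path for the matrix; the sidecar is `<path>.json`.
#' @param meta named list written to the sidecar.
#' @export
write_waveform_matrix <- function(mat, path, meta = list()) {
  utils::write.table(format(mat, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = ",")
  meta$dim <- dim(mat)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_waveform_matrix
#' @export
read_waveform_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  mat <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(mat) <- NULL
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  attr(mat, "meta") <- meta
  mat
}

#' Write a trigger-event log as delimited text
#'
#' @param events list of `trigger_event`s.
#' @param path file path.
#' @export
write_trigger_log <- function(events, path) {
  df <- do.call(rbind, lapply(events, function(e) {
    data.frame(t_request = e$t_request, t_fire = e$t_fire,
               fall_type = e$fall_type, mechanism = e$mechanism,
               duration_ms = e$duration_ms, segment = e$segment_at_fire)
  }))
  if (is.null(df)) {
    df <- data.frame(t_request = numeric(0), t_fire = numeric(0),
                     fall_type = character(0), mechanism = character(0),
                     duration_ms = numeric(0), segment = integer(0))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trigger_log
#' @export
read_trigger_log <- function(path) {
  df <- read_delim_checked(path, c("t_request", "t_fire", "fall_type",
                                   "mechanism", "duration_ms", "segment"))
  check_numeric_cols(df, c("t_request", "t_fire", "duration_ms", "segment"),
                     path)
}

#' Write a null-dataset array as dense text with a JSON header
#'
#' @param arr array from [generate_null_dataset()].
#' @param path matrix file; dims/seed/spec go to `<path>.json`.
#' @param spec the generating [null_dataset_spec()].
#' @export
write_null_dataset <- function(arr, path, spec) {
  mat <- matrix(arr, prod(dim(arr)[1:3]), dim(arr)[4])
  meta <- list(dims = dim(arr), seed = spec$seed,
               spec = spec[c("n_subjects", "n_conditions", "n_replicates",
                             "n_nodes", "fwhm", "subject_offset_sd")])
  write_waveform_matrix(mat, path, meta)
}

# deterministic polynomial hash of a config (over its canonical JSON), for
# artifact provenance stamping
config_hash <- function(config) {
  drop_fn <- function(x) {
    if (is.function(x)) return("<function>")
    if (is.list(x)) return(lapply(x, drop_fn))
    x
  }
  s <- jsonlite::toJSON(drop_fn(unclass(config)), auto_unbox = TRUE,
                        digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
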