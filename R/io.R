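#' Write / read a trial recording
#'
#' A recording is persisted as a comma-delimited table of the ten channels
#' (`t, z_L, z_R, F_L, F_R, FB_L, FB_R, z_board, theta, x_ball`, SI units,
#' one row per sample) plus a JSON metadata sidecar (`<path>.json`)
#' holding the trial metadata and the parameter snapshot. Channel values
#' are serialized with 17 significant digits, so the round trip is exact
#' for IEEE doubles.
#'
#' @param rec a `bb_recording`.
#' @param path file path for the channel table (the sidecar gets
#'   `.json` appended).
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the `bb_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "bb_recording"))
  fmt <- as.data.frame(lapply(rec, function(col) sprintf("%.17g", col)))
  names(fmt) <- names(rec)
  utils::write.table(fmt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  meta <- rec_meta(rec)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

recording_channels <- function() {
  c("t", "z_L", "z_R", "F_L", "F_R", "FB_L", "FB_R", "z_board", "theta",
    "x_ball")
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing metadata sidecar: ", side)
  df <- utils::read.csv(path, colClasses = "numeric")
  missing <- setdiff(recording_channels(), names(df))
  if (length(missing))
    stop("recording is missing required column(s): ",
         paste(missing, collapse = ", "))
  dtv <- diff(df$t)
  if (any(dtv <= 0) || (length(dtv) > 1 && diff(range(dtv)) > 1e-9))
    stop("non-uniform or non-increasing timebase in ", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$condition) || !meta$condition %in% haptic_labels())
    stop("metadata condition label must be one of: ",
         paste(haptic_labels(), collapse = ", "))
  if (!is.null(meta$params)) meta$params <- do.call(model_params, meta$params)
  new_recording(df, meta)
}

#' Write / read an unrelated-force profile
#'
#' Two-column delimited table (`FB_L`, `FB_R`) at the profile's sampling
#' rate, full numeric precision.
#'
#' @param profile an [unrelated_profile()].
#' @param path file path.
#' @param dt,ramp_duration passed to [unrelated_profile()] when reading.
#' @return `write_profile` returns `path` invisibly; `read_profile` the
#'   `bb_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "bb_profile"))
  fmt <- data.frame(FB_L = sprintf("%.17g", profile$FB_L),
                    FB_R = sprintf("%.17g", profile$FB_R))
  utils::write.table(fmt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, dt = 0.001, ramp_duration = 0.1) {
  df <- utils::read.csv(path, colClasses = "numeric")
  unrelated_profile(df$FB_L, df$FB_R, dt = dt, ramp_duration = ramp_duration)
}
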