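#' Construct a 2D marker trajectory
#'
#' A trajectory is the time-stamped path of one tracked marker in the
#' horizontal plane: strictly increasing time in seconds, x/y positions in
#' meters (origin at the room center), and the nominal sampling rate of the
#' capture system.
#'
#' @param t Numeric vector of time stamps in seconds, strictly increasing.
#' @param x,y Numeric vectors of positions in meters, same length as `t`.
#' @param rate Nominal sampling rate in Hz (e.g. 180 for optical motion
#'   capture).
#' @param marker_id Opaque marker label.
#' @return An object of class `trajectory`: a list with elements `t`, `x`,
#'   `y`, `rate`, `marker_id`.
#' @examples
#' tr <- trajectory(t = 0:99 / 180, x = 0:99 / 180 * 0.5, y = rep(0, 100),
#'                  rate = 180)
#' duration(tr)
#' @export
trajectory <- function(t, x, y, rate, marker_id = "m1") {
  obj <- structure(
    list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         rate = as.numeric(rate), marker_id = as.character(marker_id)[1]),
    class = "trajectory"
  )
  validate_trajectory(obj)
  obj
}

#' Validate trajectory invariants
#'
#' Checks strict monotonicity of time, finiteness of coordinates, positive
#' sampling rate and minimum length (2 samples).
#'
#' @param traj A `trajectory`.
#' @return `traj`, invisibly. Errors if an invariant is violated.
#' @export
validate_trajectory <- function(traj) {
  if (!inherits(traj, "trajectory")) stop("not a trajectory object")
  n <- length(traj$t)
  if (n < 2) stop("trajectory must have at least 2 samples")
  if (length(traj$x) != n || length(traj$y) != n)
    stop("t, x, y must have equal length")
  if (!all(is.finite(traj$t))) stop("non-finite time stamps")
  if (any(diff(traj$t) <= 0))
    stop("time stamps must be strictly increasing")
  if (!all(is.finite(traj$x)) || !all(is.finite(traj$y)))
    stop("non-finite coordinates")
  if (!is.finite(traj$rate) || traj$rate <= 0) stop("rate must be > 0")
  invisible(traj)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> marker '%s': %d samples, %.3f s at %g Hz\n",
              x$marker_id, length(x$t), duration(x), x$rate))
  cat(sprintf("  x range [%.3f, %.3f] m, y range [%.3f, %.3f] m\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_s = x$t, x_m = x$x, y_m = x$y,
             marker_id = x$marker_id, stringsAsFactors = FALSE)
}

#' Trajectory duration in seconds
#' @param traj A `trajectory`.
#' @return Elapsed time between first and last sample, seconds.
#' @export
duration <- function(traj) {
  traj$t[length(traj$t)] - traj$t[1]
}

#' Column-mapping dialect for trajectory tables
#'
#' Describes how columns of a delimited text file map onto trajectory
#' fields. Files may carry either a time column (seconds) or a frame-index
#' column; frame indices are converted to seconds via the sampling rate.
#'
#' @param time Name of the time column (seconds), or `NULL` if the file is
#'   frame-indexed.
#' @param frame Name of the frame-index column used when `time` is absent.
#' @param x,y Names of the coordinate columns (meters).
#' @param marker Name of the marker-label column (optional in the file).
#' @param rate_col Name of a per-file sampling-rate column (optional).
#' @param rate Fallback sampling rate in Hz when the file has no rate
#'   column; required for frame-indexed files.
#' @param sep Field separator.
#' @return A list of class `trajectory_dialect`.
#' @export
trajectory_dialect <- function(time = "time_s", frame = "frame",
                               x = "x_m", y = "y_m",
                               marker = "marker_id", rate_col = "rate_hz",
                               rate = NULL, sep = ",") {
  structure(list(time = time, frame = frame, x = x, y = y, marker = marker,
                 rate_col = rate_col, rate = rate, sep = sep),
            class = "trajectory_dialect")
}

#' Read a trajectory from a delimited text file
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect A [trajectory_dialect()] mapping file columns to fields.
#' @return A [trajectory()].
#' @examples
#' tr <- trajectory(0:9 / 180, 0:9 * 0.01, rep(0, 10), rate = 180)
#' f <- tempfile(fileext = ".csv")
#' write_trajectory(tr, f)
#' tr2 <- read_trajectory(f)
#' @export
read_trajectory <- function(path, dialect = trajectory_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = dialect$sep, stringsAsFactors = FALSE)
  if (!(dialect$x %in% names(df)) || !(dialect$y %in% names(df)))
    stop("format error: missing coordinate columns '", dialect$x, "'/'",
         dialect$y, "'")
  rate <- dialect$rate
  if (!is.null(dialect$rate_col) && dialect$rate_col %in% names(df))
    rate <- df[[dialect$rate_col]][1]
  has_time <- !is.null(dialect$time) && dialect$time %in% names(df)
  if (has_time) {
    t <- df[[dialect$time]]
    if (is.null(rate)) {
      dt <- diff(t)
      if (any(dt <= 0)) stop("validation error: time not strictly increasing")
      rate <- 1 / median(dt)
    }
  } else {
    if (is.null(dialect$frame) || !(dialect$frame %in% names(df)))
      stop("format error: neither time column '", dialect$time,
           "' nor frame column '", dialect$frame, "' present")
    if (is.null(rate))
      stop("format error: frame-indexed file requires a sampling rate")
    t <- df[[dialect$frame]] / rate
  }
  if (any(diff(t) <= 0))
    stop("validation error: time not strictly increasing (duplicate or ",
         "reordered samples)")
  marker <- if (!is.null(dialect$marker) && dialect$marker %in% names(df))
    df[[dialect$marker]][1] else "m1"
  trajectory(t = t, x = df[[dialect$x]], y = df[[dialect$y]],
             rate = rate, marker_id = marker)
}

#' Write a trajectory to a CSV file
#'
#' Writes the standard dialect (`time_s`, `x_m`, `y_m`, `marker_id`,
#' `rate_hz`); the file round-trips through [read_trajectory()].
#'
#' @param traj A valid [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  validate_trajectory(traj)
  if (!is.character(path) || length(path) != 1 || !nzchar(path))
    stop("invalid output path")
  df <- as.data.frame(traj)
  df$rate_hz <- traj$rate
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Detect sampling gaps in a trajectory
#'
#' Optical tracking drops samples when markers are occluded; this reports
#' every pair of consecutive samples whose spacing exceeds `max_dt`.
#'
#' @param traj A `trajectory`.
#' @param max_dt Maximum tolerated inter-sample spacing, seconds (> 0).
#' @return A data frame with columns `gap_start`, `gap_end`, `gap_length`
#'   (seconds); zero rows if the stream has no gaps.
#' @export
detect_gaps <- function(traj, max_dt) {
  validate_trajectory(traj)
  stopifnot(max_dt > 0)
  dt <- diff(traj$t)
  i <- which(dt > max_dt)
  data.frame(gap_start = traj$t[i], gap_end = traj$t[i + 1],
             gap_length = dt[i])
}

#' Fill short sampling gaps by linear interpolation
#'
#' Gaps no longer than `max_fill` are filled with linearly interpolated
#' samples on the nominal `1/rate` grid; longer gaps are left intact and
#' reported in the `unfilled_gaps` attribute. Samples present in the input
#' are never altered.
#'
#' @param traj A `trajectory`.
#' @param max_fill Longest gap (seconds) that may be interpolated; gaps
#'   above this are considered tracking failures, not jitter.
#' @return A `trajectory` with attribute `unfilled_gaps` (data frame as
#'   returned by [detect_gaps()] for the gaps that were left).
#' @export
fill_gaps <- function(traj, max_fill) {
  validate_trajectory(traj)
  stopifnot(max_fill >= 0)
  dt_nom <- 1 / traj$rate
  gaps <- detect_gaps(traj, max_dt = dt_nom * 1.5)
  fill <- gaps[gaps$gap_length <= max_fill, , drop = FALSE]
  left <- gaps[gaps$gap_length > max_fill, , drop = FALSE]
  if (nrow(fill) == 0) {
    attr(traj, "unfilled_gaps") <- left
    return(traj)
  }
  new_t <- unlist(lapply(seq_len(nrow(fill)), function(i) {
    s <- seq(fill$gap_start[i] + dt_nom, fill$gap_end[i], by = dt_nom)
    s[s < fill$gap_end[i] - dt_nom * 1e-6]
  }))
  out_t <- sort(c(traj$t, new_t))
  out <- trajectory(
    t = out_t,
    x = approx(traj$t, traj$x, xout = out_t)$y,
    y = approx(traj$t, traj$y, xout = out_t)$y,
    rate = traj$rate, marker_id = traj$marker_id
  )
  attr(out, "unfilled_gaps") <- left
  out
}

#' Extract a time slice of a trajectory
#'
#' @param traj A `trajectory`.
#' @param start_time,end_time Bounds in seconds (same clock as `traj$t`).
#' @param rezero If `TRUE`, shift time so the slice starts at 0.
#' @return A `trajectory` covering `[start_time, end_time]`.
#' @export
slice_trajectory <- function(traj, start_time, end_time, rezero = FALSE) {
  validate_trajectory(traj)
  if (end_time <= start_time) stop("end_time must exceed start_time")
  keep <- traj$t >= start_time & traj$t <= end_time
  if (sum(keep) < 2) stop("slice contains fewer than 2 samples")
  t <- traj$t[keep]
  if (rezero) t <- t - t[1]
  trajectory(t = t, x = traj$x[keep], y = traj$y[keep],
             rate = traj$rate, marker_id = traj$marker_id)
}

#' Read an observation manifest
#'
#' The manifest assigns each recording segment to its design cell: sound
#' model (S1/S2/S3), participant, group, session (1 or 2) and observation
#' number (1..12), plus the segment's start and end times in the parent
#' recording.
#'
#' @param path CSV file with columns `segment_id`, `sound_model`,
#'   `participant_id`, `group_id`, `session`, `observation_number`,
#'   `start_time`, `end_time`.
#' @return A validated data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_manifest(read.csv(path, stringsAsFactors = FALSE))
}

#' Validate an observation manifest
#'
#' @param manifest A data frame with the manifest columns.
#' @return The manifest, invisibly usable; errors on violations.
#' @export
validate_manifest <- function(manifest) {
  need <- c("segment_id", "sound_model", "participant_id", "group_id",
            "session", "observation_number", "start_time", "end_time")
  miss <- setdiff(need, names(manifest))
  if (length(miss) > 0)
    stop("format error: manifest missing columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$segment_id))
    stop("validation error: duplicate segment_ids")
  if (!all(manifest$sound_model %in% c("S1", "S2", "S3")))
    stop("validation error: sound_model must be S1, S2 or S3")
  if (!all(manifest$end_time > manifest$start_time))
    stop("validation error: end_time must exceed start_time")
  if (!all(manifest$observation_number == round(manifest$observation_number)) ||
      any(manifest$observation_number < 1))
    stop("validation error: observation_number must be a positive integer")
  if (!all(manifest$session %in% c(1, 2)))
    stop("validation error: session must be 1 or 2")
  manifest
}
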