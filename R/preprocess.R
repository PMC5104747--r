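#' Trim an observation to its steady middle part
#'
#' Recording segments include fades and transient reorientation at the
#' start and end of each sound-model presentation; analysis uses only the
#' middle excerpt. With the default 6 s lead and tail, a 37 s segment
#' yields a 25 s excerpt.
#'
#' @param traj A `trajectory` covering one observation.
#' @param lead Seconds removed from the start (default 6).
#' @param tail Seconds removed from the end (default 6).
#' @return The trimmed `trajectory` (original time stamps preserved).
#' @export
trim_observation <- function(traj, lead = 6, tail = 6) {
  validate_trajectory(traj)
  stopifnot(lead >= 0, tail >= 0)
  dur <- duration(traj)
  if (dur <= lead + tail)
    stop("too-short segment: duration ", round(dur, 3),
         " s <= lead + tail = ", lead + tail, " s")
  if (lead == 0 && tail == 0) return(traj)
  t0 <- traj$t[1]
  slice_trajectory(traj, t0 + lead, t0 + dur - tail)
}

#' Flag marker crossover by implausible inter-sample speed
#'
#' When the tracker mistakes one marker for another, the labelled
#' trajectory jumps across the room between consecutive frames. Any
#' consecutive-sample displacement implying a speed above `v_max` flags
#' the segment.
#'
#' @param traj A `trajectory`.
#' @param v_max Speed threshold in m/s; default 10 (far above child
#'   locomotion, far below marker-swap jumps).
#' @return `TRUE` iff any raw inter-sample speed exceeds `v_max`.
#' @export
flag_crossover <- function(traj, v_max = 10) {
  validate_trajectory(traj)
  stopifnot(v_max > 0)
  dt <- diff(traj$t)
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  any(step / dt > v_max)
}

#' Exclusion rules for observation quality control
#'
#' @param v_max Crossover speed threshold, m/s.
#' @param min_fraction Minimum retained fraction of the nominal sample
#'   count (`nominal_duration * rate`); segments with fewer samples are
#'   excluded as under-tracked.
#' @param nominal_duration Nominal excerpt duration in seconds (25).
#' @param max_out_of_area_fraction Maximum tolerated fraction of samples
#'   outside the trackable area.
#' @param area Width and height (meters) of the trackable area, centered
#'   at the origin. Default 4.66 x 5.40 m.
#' @return A list of class `exclusion_rules`.
#' @export
exclusion_rules <- function(v_max = 10, min_fraction = 0.5,
                            nominal_duration = 25,
                            max_out_of_area_fraction = 0.2,
                            area = c(width = 4.66, height = 5.40)) {
  structure(list(v_max = v_max, min_fraction = min_fraction,
                 nominal_duration = nominal_duration,
                 max_out_of_area_fraction = max_out_of_area_fraction,
                 area = area),
            class = "exclusion_rules")
}

#' Apply observation exclusion rules
#'
#' Screens per-observation segments for marker crossover, insufficient
#' tracking (too few samples) and out-of-area movement, mirroring the
#' manual cleaning of motion-capture studies. Every excluded segment
#' carries a reason; kept and excluded segments partition the input.
#'
#' @param segments A list; each element is a list with components `traj`
#'   (a `trajectory`) and `meta` (a one-row data frame with at least
#'   `segment_id`).
#' @param rules An [exclusion_rules()] object.
#' @return A list with `kept` (the surviving elements of `segments`) and
#'   `report` (a data frame with one quality row per input segment:
#'   `segment_id`, `n_samples`, `crossover_flag`, `out_of_area_fraction`,
#'   `longest_gap`, `excluded`, `reason`).
#' @export
apply_exclusions <- function(segments, rules = exclusion_rules()) {
  stopifnot(inherits(rules, "exclusion_rules"))
  half_w <- rules$area[[1]] / 2
  half_h <- rules$area[[2]] / 2
  rows <- lapply(segments, function(seg) {
    traj <- seg$traj
    validate_trajectory(traj)
    n <- length(traj$t)
    cross <- flag_crossover(traj, rules$v_max)
    out_frac <- mean(abs(traj$x) > half_w | abs(traj$y) > half_h)
    gaps <- detect_gaps(traj, max_dt = 1.5 / traj$rate)
    longest_gap <- if (nrow(gaps) > 0) max(gaps$gap_length) else 0
    min_n <- rules$min_fraction * rules$nominal_duration * traj$rate
    reason <- ""
    if (cross) {
      reason <- "crossover"
    } else if (n < min_n) {
      reason <- "too_few_samples"
    } else if (out_frac > rules$max_out_of_area_fraction) {
      reason <- "out_of_area"
    }
    data.frame(segment_id = as.character(seg$meta$segment_id[1]),
               n_samples = n, crossover_flag = cross,
               out_of_area_fraction = out_frac, longest_gap = longest_gap,
               excluded = nzchar(reason), reason = reason,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(kept = segments[!report$excluded], report = report)
}

#' Normalize a feature vector to the unit range
#'
#' Affine min-max scaling applied per feature over the whole retained
#' dataset (pooled across participants), so between-participant contrasts
#' are preserved for the mixed-model stage.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return The vector rescaled so `min = 0` and `max = 1` exactly.
#' @export
normalize_unit_range <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) stop("need at least two finite values")
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("degenerate input: constant vector cannot be scaled")
  (values - lo) / (hi - lo)
}
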