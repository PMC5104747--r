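# Movement-quality indices summarised per observation: smoothness from the
# curvature-velocity coupling, directness from path geometry.

# Correlation statistic for one window of log-curvature / log-speed
# samples. Returns NA when either log series has zero variance.
window_statistic <- function(lk, lv, variant) {
  s_lk <- sd(lk)
  s_lv <- sd(lv)
  if (!is.finite(s_lk) || !is.finite(s_lv) || s_lk == 0 || s_lv == 0)
    return(NA_real_)
  if (variant == "pearson") cor(lk, lv) else 1 / (s_lk * s_lv)
}

#' Windowed Smoothness Index
#'
#' Smooth movement obeys a lawful coupling between path curvature and
#' speed (slowing into bends, the two-thirds power law); over short
#' windows this makes `log k` and `log v` nearly collinear. The index is
#' computed over consecutive non-overlapping windows of `window` seconds:
#'
#' * `variant = "pearson"`: the Pearson correlation of `log |k|` and
#'   `log v` within the window, in `[-1, 1]`. Lawful smooth movement
#'   drives the magnitude toward 1 (negative sign for the power law).
#' * `variant = "simplified"`: `1 / (sd(log |k|) * sd(log v))`, the
#'   approximation obtained by treating the covariance as unity. It is
#'   positive, unbounded, and scale-dependent; it is provided for
#'   completeness but the Pearson form is the default and the one whose
#'   values are comparable across datasets.
#'
#' Windows need at least 3 valid samples (speed above the floor, nonzero
#' curvature); windows failing that, or with zero variance in either log
#' series, yield `NA` rather than an error.
#'
#' @inheritParams kinematics
#' @param window Window length in seconds (default 0.030).
#' @param variant `"pearson"` (default) or `"simplified"`.
#' @return A data frame with one row per window: `window` (index),
#'   `t_start`, `n_valid`, `si`.
#' @export
smoothness_index <- function(traj, window = 0.030,
                             variant = c("pearson", "simplified"),
                             smooth_frames = 5, v_floor = 1e-3) {
  variant <- match.arg(variant)
  stopifnot(window > 0)
  kin <- kinematics(traj, smooth_frames, v_floor)
  idx <- floor((kin$t - kin$t[1]) / window)
  valid <- is.finite(kin$k) & abs(kin$k) > 0 & kin$v > v_floor
  wins <- sort(unique(idx))
  si <- vapply(wins, function(w) {
    sel <- idx == w & valid
    if (sum(sel) < 3) return(NA_real_)
    window_statistic(log(abs(kin$k[sel])), log(kin$v[sel]), variant)
  }, numeric(1))
  n_valid <- vapply(wins, function(w) sum(idx == w & valid), integer(1))
  out <- data.frame(window = wins, t_start = kin$t[1] + wins * window,
                    n_valid = n_valid, si = si)
  attr(out, "variant") <- variant
  attr(out, "window") <- window
  out
}

#' Directness Index of a trajectory
#'
#' Ratio of the straight-line (chord) distance between the first and last
#' points to the summed lengths of all path segments. By the triangle
#' inequality it lies in `[0, 1]`: 1 for a perfectly direct (rectilinear,
#' monotone) path, approaching 0 for meandering or closed paths.
#'
#' @param traj A `trajectory`.
#' @return A scalar in `[0, 1]`.
#' @export
directness_index <- function(traj) {
  validate_trajectory(traj)
  path <- sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
  if (path == 0) stop("no-motion error: zero path length")
  n <- length(traj$x)
  chord <- sqrt((traj$x[n] - traj$x[1])^2 + (traj$y[n] - traj$y[1])^2)
  chord / path
}

#' Summarize movement-quality features for one observation
#'
#' Computes per-observation means of the Energy Index (over frames) and
#' Smoothness Index (over valid windows), and the Directness Index of the
#' whole excerpt treated as one movement unit. `SI_absmean` is the mean
#' correlation magnitude, the orientation-free smoothness summary used
#' when comparing movement styles.
#'
#' @inheritParams smoothness_index
#' @param labels Optional one-row data frame of design labels (e.g. a
#'   manifest row: `segment_id`, `sound_model`, `participant_id`,
#'   `group_id`, `session`, `observation_number`) bound onto the result.
#' @return A one-row data frame: the label columns (if given) followed by
#'   `EI_mean`, `SI_mean`, `SI_absmean`, `n_windows`, `DI`.
#' @export
summarize_features <- function(traj, labels = NULL, window = 0.030,
                               variant = c("pearson", "simplified"),
                               smooth_frames = 5, v_floor = 1e-3) {
  variant <- match.arg(variant)
  ei <- mean(energy_index(traj, smooth_frames, v_floor))
  si <- smoothness_index(traj, window, variant, smooth_frames, v_floor)$si
  si_ok <- si[is.finite(si)]
  feats <- data.frame(
    EI_mean = ei,
    SI_mean = if (length(si_ok) > 0) mean(si_ok) else NA_real_,
    SI_absmean = if (length(si_ok) > 0) mean(abs(si_ok)) else NA_real_,
    n_windows = length(si_ok),
    DI = directness_index(traj)
  )
  if (is.null(labels)) return(feats)
  cbind(as.data.frame(labels, stringsAsFactors = FALSE), feats,
        row.names = NULL)
}

#' Build a feature table from quality-controlled segments
#'
#' Convenience wrapper: trims each kept segment, summarizes its features
#' and binds the manifest labels, yielding the table consumed by the
#' mixed-model stage.
#'
#' @param kept List of segments as returned in `apply_exclusions()$kept`
#'   (each with `traj` and `meta`).
#' @param trim If `TRUE` (default) apply [trim_observation()] with `lead`
#'   and `tail`.
#' @param lead,tail Trim margins in seconds.
#' @inheritParams summarize_features
#' @return A data frame with one row per segment.
#' @export
features_from_segments <- function(kept, trim = TRUE, lead = 6, tail = 6,
                                   window = 0.030,
                                   variant = c("pearson", "simplified"),
                                   smooth_frames = 5, v_floor = 1e-3) {
  variant <- match.arg(variant)
  rows <- lapply(kept, function(seg) {
    traj <- if (trim) trim_observation(seg$traj, lead, tail) else seg$traj
    summarize_features(traj, labels = seg$meta, window = window,
                       variant = variant, smooth_frames = smooth_frames,
                       v_floor = v_floor)
  })
  do.call(rbind, rows)
}
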