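# Low-level kinematic estimation: zero-phase smoothing, finite-difference
# derivatives, speed and signed curvature.

# Zero-phase moving average with edge replication; w is in frames and is
# forced odd so the filter introduces no phase shift.
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  if (w %% 2 == 0) w <- w + 1
  n <- length(x)
  pad <- (w - 1) / 2
  xp <- c(rep(x[1], pad), x, rep(x[n], pad))
  y <- as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))
  y[(pad + 1):(pad + n)]
}

# Central finite differences on a possibly non-uniform grid; one-sided at
# the end points.
fd_derivative <- function(t, p) {
  n <- length(p)
  if (n < 3) stop("too-short trajectory: need at least 3 samples")
  d <- numeric(n)
  d[1] <- (p[2] - p[1]) / (t[2] - t[1])
  d[n] <- (p[n] - p[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  d[i] <- (p[i + 1] - p[i - 1]) / (t[i + 1] - t[i - 1])
  d
}

#' Per-frame kinematic series of a trajectory
#'
#' Estimates first and second position derivatives by central finite
#' differences after zero-phase moving-average smoothing, then derives
#' speed `v = sqrt(xdot^2 + ydot^2)` and signed planar curvature
#' `k = (xdot * yddot - ydot * xddot) / v^3`. Curvature is masked (`NA`)
#' wherever speed does not exceed `v_floor`, since the formula's
#' denominator (and `log v` downstream) degenerates at rest.
#'
#' @param traj A `trajectory` with at least 3 samples (5 for usable
#'   curvature).
#' @param smooth_frames Width of the zero-phase moving average in frames
#'   (default 5; 1 disables smoothing). Reported in the result's
#'   attributes so output metadata can record it.
#' @param v_floor Speed floor in m/s below which curvature is masked
#'   (default 1e-3).
#' @return A data frame with columns `t`, `x`, `y`, `vx`, `vy`, `ax`,
#'   `ay`, `v`, `k`; attributes `smooth_frames`, `v_floor`, `rate`.
#' @export
kinematics <- function(traj, smooth_frames = 5, v_floor = 1e-3) {
  validate_trajectory(traj)
  if (length(traj$t) < 3) stop("too-short trajectory: need >= 3 samples")
  xs <- moving_average(traj$x, smooth_frames)
  ys <- moving_average(traj$y, smooth_frames)
  vx <- fd_derivative(traj$t, xs)
  vy <- fd_derivative(traj$t, ys)
  ax <- fd_derivative(traj$t, vx)
  ay <- fd_derivative(traj$t, vy)
  v <- sqrt(vx^2 + vy^2)
  k <- rep(NA_real_, length(v))
  ok <- v > v_floor
  k[ok] <- (vx[ok] * ay[ok] - vy[ok] * ax[ok]) / v[ok]^3
  out <- data.frame(t = traj$t, x = xs, y = ys, vx = vx, vy = vy,
                    ax = ax, ay = ay, v = v, k = k)
  attr(out, "smooth_frames") <- smooth_frames
  attr(out, "v_floor") <- v_floor
  attr(out, "rate") <- traj$rate
  out
}

#' Instantaneous speed of a trajectory
#'
#' First derivative magnitude of the tracked point,
#' `v(f) = sqrt(xdot(f)^2 + ydot(f)^2)`, in m/s.
#'
#' @inheritParams kinematics
#' @return Numeric vector of speeds, one per sample.
#' @export
speed <- function(traj, smooth_frames = 5, v_floor = 1e-3) {
  kinematics(traj, smooth_frames, v_floor)$v
}

#' Signed planar curvature of a trajectory
#'
#' `k = (xdot * yddot - ydot * xddot) / (xdot^2 + ydot^2)^(3/2)`, in 1/m:
#' the reciprocal of the local osculating-circle radius, signed by turn
#' direction. A straight path has zero curvature; sharp bends have high
#' magnitude. Samples at or below the speed floor are `NA`.
#'
#' @inheritParams kinematics
#' @return Numeric vector of curvatures (possibly `NA`), one per sample.
#' @export
curvature <- function(traj, smooth_frames = 5, v_floor = 1e-3) {
  if (length(traj$t) < 5) stop("too-short trajectory: need >= 5 samples")
  k <- kinematics(traj, smooth_frames, v_floor)$k
  if (all(is.na(k)))
    stop("no-motion error: all samples at or below the speed floor")
  k
}

#' Per-frame Energy Index
#'
#' Kinetic-energy proxy of the tracked head point with unit mass and a
#' single tracked joint: `EI(f) = v(f)^2 / 2`.
#'
#' @inheritParams kinematics
#' @return Numeric vector, one value per sample, dimension (m/s)^2.
#' @export
energy_index <- function(traj, smooth_frames = 5, v_floor = 1e-3) {
  0.5 * speed(traj, smooth_frames, v_floor)^2
}
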