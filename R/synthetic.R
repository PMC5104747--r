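# Synthetic trajectories and cohort-structured feature tables with known
# ground truth, emulating free movement of children in a 4.66 x 5.40 m
# tracked area captured at 180 fps.

# Integrate per-frame velocities into positions with specular reflection
# at the area walls; flips the corresponding velocity sign state on
# reflection so kinematics stay stationary without trapping at walls.
integrate_reflecting <- function(vx, vy, dt, x0, y0, half_w, half_h) {
  n <- length(vx)
  x <- numeric(n); y <- numeric(n)
  x[1] <- x0; y[1] <- y0
  sx <- 1; sy <- 1
  for (i in 2:n) {
    xi <- x[i - 1] + sx * vx[i] * dt
    yi <- y[i - 1] + sy * vy[i] * dt
    if (xi > half_w) { xi <- 2 * half_w - xi; sx <- -sx }
    if (xi < -half_w) { xi <- -2 * half_w - xi; sx <- -sx }
    if (yi > half_h) { yi <- 2 * half_h - yi; sy <- -sy }
    if (yi < -half_h) { yi <- -2 * half_h - yi; sy <- -sy }
    x[i] <- xi; y[i] <- yi
  }
  list(x = x, y = y)
}

#' Generate a synthetic 2D trajectory of a given movement style
#'
#' Emulates head trajectories of a child moving in the tracked area.
#' Styles:
#'
#' * `"smooth"` — velocity follows an Ornstein-Uhlenbeck process with
#'   persistence time `persistence_time`, low-passed over
#'   `smoothing_time`: sweeping, continuously curving paths with lawful
#'   curvature-velocity coupling.
#' * `"jerky"` — piecewise-constant headings with abrupt turns arriving
#'   at rate `turn_rate` per second (with probability `reversal_prob` a
#'   turn is a near-reversal, the back-and-forth shuffling typical of
#'   stop-start movement), per-segment speeds, and full stops (speed
#'   exactly 0) arriving at rate `pause_prob` per second, so the
#'   silence-at-rest property of the sound models is exercised end to
#'   end.
#' * `"straight"`, `"circle"`, `"square"` — analytic fixtures (exact
#'   line at constant speed; circle of radius `radius`; axis-aligned
#'   square contour), used as closed-form oracles.
#'
#' Stochastic styles are confined to the area by specular reflection at
#' the walls; their speeds are rescaled so the empirical mean speed
#' equals `mean_speed`.
#'
#' @param style One of `"smooth"`, `"jerky"`, `"straight"`, `"circle"`,
#'   `"square"`.
#' @param mean_speed Target mean speed, m/s (default 0.35: the average
#'   head speed of a young child moving freely, including stops, is well
#'   below walking speed).
#' @param duration Length in seconds (default 36, one observation before
#'   trimming).
#' @param rate Sampling rate, Hz (default 180).
#' @param area Width and height of the tracked area, meters.
#' @param turn_rate Expected abrupt-turn frequency, 1/s (jerky).
#' @param pause_prob Expected stop frequency, 1/s (jerky).
#' @param reversal_prob Probability that an abrupt turn reverses the
#'   heading rather than redrawing it uniformly (jerky).
#' @param smoothing_time Low-pass window, seconds (smooth).
#' @param persistence_time Ornstein-Uhlenbeck velocity relaxation time,
#'   seconds (smooth); long persistence gives sweeping, direct paths.
#' @param radius Circle radius, meters (circle).
#' @param side Square side, meters (square).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return A [trajectory()] with `marker_id` set to the style name.
#' @export
gen_trajectory <- function(style = c("smooth", "jerky", "straight",
                                     "circle", "square"),
                           mean_speed = 0.35, duration = 36, rate = 180,
                           area = c(4.66, 5.40), turn_rate = 3,
                           pause_prob = 0.25, reversal_prob = 0.5,
                           smoothing_time = 0.4, persistence_time = 10,
                           radius = 0.8, side = 2, seed = NULL) {
  style <- match.arg(style)
  stopifnot(mean_speed >= 0, duration > 0, rate > 0, all(area > 0))
  n <- floor(duration * rate) + 1
  t <- (seq_len(n) - 1) / rate
  half_w <- area[1] / 2
  half_h <- area[2] / 2

  if (style == "straight") {
    len <- mean_speed * duration
    diag_len <- sqrt(area[1]^2 + area[2]^2) * 0.9
    if (len > diag_len)
      stop("straight path of ", round(len, 2), " m does not fit the area")
    ux <- area[1] / sqrt(area[1]^2 + area[2]^2)
    uy <- area[2] / sqrt(area[1]^2 + area[2]^2)
    x <- -ux * len / 2 + ux * mean_speed * t
    y <- -uy * len / 2 + uy * mean_speed * t
    return(trajectory(t, x, y, rate, marker_id = "straight"))
  }
  if (style == "circle") {
    if (radius > min(half_w, half_h))
      stop("circle radius exceeds the area")
    omega <- mean_speed / radius
    return(trajectory(t, radius * cos(omega * t), radius * sin(omega * t),
                      rate, marker_id = "circle"))
  }
  if (style == "square") {
    half <- side / 2
    corners <- cbind(c(-half, half, half, -half, -half),
                     c(-half, -half, half, half, -half))
    s_along <- (mean_speed * t) %% (4 * side)
    leg <- pmin(floor(s_along / side), 3)
    u <- s_along / side - leg
    x <- corners[leg + 1, 1] + u * (corners[leg + 2, 1] - corners[leg + 1, 1])
    y <- corners[leg + 1, 2] + u * (corners[leg + 2, 2] - corners[leg + 1, 2])
    return(trajectory(t, x, y, rate, marker_id = "square"))
  }

  gen <- function() {
    dt <- 1 / rate
    if (style == "smooth") {
      tau <- persistence_time
      vx <- numeric(n); vy <- numeric(n)
      zx <- rnorm(n); zy <- rnorm(n)
      vx[1] <- rnorm(1, 0, mean_speed)
      vy[1] <- rnorm(1, 0, mean_speed)
      for (i in 2:n) {
        vx[i] <- vx[i - 1] * (1 - dt / tau) +
          mean_speed * sqrt(2 * dt / tau) * zx[i]
        vy[i] <- vy[i - 1] * (1 - dt / tau) +
          mean_speed * sqrt(2 * dt / tau) * zy[i]
      }
      w <- max(1, round(smoothing_time * rate))
      vx <- moving_average(vx, w)
      vy <- moving_average(vy, w)
    } else { # jerky
      heading <- runif(1, 0, 2 * pi)
      seg_speed <- rlnorm(1, log(mean_speed), 0.4)
      vx <- numeric(n); vy <- numeric(n)
      next_turn <- rexp(1, turn_rate)
      next_pause <- rexp(1, pause_prob)
      pause_until <- -1
      tt <- 0
      for (i in seq_len(n)) {
        if (tt >= next_pause && tt > pause_until) {
          pause_until <- tt + runif(1, 0.3, 1.0)
          next_pause <- pause_until + rexp(1, pause_prob)
        }
        if (tt >= next_turn) {
          heading <- if (runif(1) < reversal_prob)
            heading + pi + runif(1, -0.5, 0.5)
          else runif(1, 0, 2 * pi)
          seg_speed <- rlnorm(1, log(mean_speed), 0.4)
          next_turn <- tt + rexp(1, turn_rate)
        }
        if (tt <= pause_until) {
          vx[i] <- 0; vy[i] <- 0
        } else {
          vx[i] <- seg_speed * cos(heading)
          vy[i] <- seg_speed * sin(heading)
        }
        tt <- tt + dt
      }
    }
    sp <- sqrt(vx^2 + vy^2)
    if (mean(sp) > 0) {
      f <- mean_speed / mean(sp)
      vx <- vx * f; vy <- vy * f
    }
    x0 <- runif(1, -half_w / 2, half_w / 2)
    y0 <- runif(1, -half_h / 2, half_h / 2)
    pos <- integrate_reflecting(vx, vy, dt, x0, y0, half_w, half_h)
    trajectory(t, pos$x, pos$y, rate, marker_id = style)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a cohort-structured feature table with known ground truth
#'
#' Generates per-observation feature values from the random-intercept
#' model `y = b0 + b_model + b_session*(session-1) + b_obs*(obs-1) +
#' u_group + u_participant + e`, with Gaussian random intercepts for
#' groups and for participants nested within groups, emulating the
#' three-level design of a sonification experiment: each participant
#' contributes `n_obs_per_cell` observations per sound model, split into
#' two sessions.
#'
#' Default variance components are the scale of normalized movement
#' features in such studies: SD 0.054 between groups, 0.052 between
#' participants, 0.168 residual; the default fixed effects place S3
#' 0.06 below S1 = S2, with small negative session and observation-number
#' slopes.
#'
#' @param n_groups Number of experiment groups (default 3).
#' @param n_participants_per_group Participants per group (default 4).
#' @param n_obs_per_cell Observations per participant and sound model
#'   (default 12; observations 1-6 in session 1, the rest in session 2).
#' @param fixed_effects Named list: `intercept`, `model` (named vector of
#'   per-sound-model offsets, S1 reference), `session` (slope for
#'   session 2 vs 1), `observation` (slope per observation number).
#' @param sd_group,sd_participant,sd_residual Random-effect and residual
#'   SDs.
#' @param seed Optional integer seed.
#' @return A data frame with columns `segment_id`, `sound_model`,
#'   `participant_id`, `group_id`, `session`, `observation_number`,
#'   `value`, and attribute `truth` (the generating parameters and the
#'   drawn random intercepts).
#' @export
gen_cohort <- function(n_groups = 3, n_participants_per_group = 4,
                       n_obs_per_cell = 12,
                       fixed_effects = list(
                         intercept = 0.3,
                         model = c(S1 = 0, S2 = 0, S3 = -0.06),
                         session = -0.043, observation = -0.009),
                       sd_group = 0.054, sd_participant = 0.052,
                       sd_residual = 0.168, seed = NULL) {
  stopifnot(n_groups >= 1, n_participants_per_group >= 1,
            n_obs_per_cell >= 1, sd_group >= 0, sd_participant >= 0,
            sd_residual >= 0)
  gen <- function() {
    models <- c("S1", "S2", "S3")
    design <- expand.grid(
      observation_number = seq_len(n_obs_per_cell),
      sound_model = models,
      participant = seq_len(n_participants_per_group),
      group = seq_len(n_groups),
      stringsAsFactors = FALSE
    )
    design$group_id <- sprintf("g%02d", design$group)
    design$participant_id <- sprintf("%s_p%02d", design$group_id,
                                     design$participant)
    half <- ceiling(n_obs_per_cell / 2)
    design$session <- ifelse(design$observation_number <= half, 1L, 2L)
    u_group <- setNames(rnorm(n_groups, 0, sd_group),
                        sprintf("g%02d", seq_len(n_groups)))
    pid <- unique(design$participant_id)
    u_part <- setNames(rnorm(length(pid), 0, sd_participant), pid)
    mu <- fixed_effects$intercept +
      fixed_effects$model[design$sound_model] +
      fixed_effects$session * (design$session - 1) +
      fixed_effects$observation * (design$observation_number - 1) +
      u_group[design$group_id] + u_part[design$participant_id]
    value <- mu + rnorm(nrow(design), 0, sd_residual)
    out <- data.frame(
      segment_id = sprintf("%s_%s_o%02d", design$participant_id,
                           design$sound_model, design$observation_number),
      sound_model = factor(design$sound_model, levels = models),
      participant_id = design$participant_id,
      group_id = design$group_id,
      session = design$session,
      observation_number = design$observation_number,
      value = as.numeric(value),
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- list(fixed_effects = fixed_effects,
                               sd_group = sd_group,
                               sd_participant = sd_participant,
                               sd_residual = sd_residual,
                               u_group = u_group, u_participant = u_part)
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
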