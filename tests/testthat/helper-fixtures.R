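# Fixtures generated in code: analytic paths with closed-form kinematics
# and a curvature-velocity power-law trajectory.

# Right-angle polyline: 1 m east then 1 m north at constant speed.
right_angle_fixture <- function(rate = 100, speed = 1) {
  n_leg <- round(rate / speed)
  t <- (0:(2 * n_leg)) / rate
  s <- speed * t
  x <- pmin(s, 1)
  y <- pmax(s - 1, 0)
  trajectory(t, x, y, rate)
}

# Trajectory obeying v = c * kappa^(-1/3) (two-thirds power law) with
# log-linear curvature profile kappa(t) = k0 * exp(a t): log k and log v
# are exactly affine in t, so every window has |correlation| 1 in truth.
powerlaw_fixture <- function(duration = 8, rate = 180, k0 = 0.3, a = 0.6,
                             cc = 0.4) {
  n <- floor(duration * rate) + 1
  t <- (seq_len(n) - 1) / rate
  kap <- k0 * exp(a * t)
  v <- cc * kap^(-1 / 3)
  dt <- 1 / rate
  theta <- cumsum(c(0, (kap * v)[-n])) * dt
  x <- cumsum(c(0, (v * cos(theta))[-n])) * dt
  y <- cumsum(c(0, (v * sin(theta))[-n])) * dt
  trajectory(t, x, y, rate)
}

# Constant-value control signal, for rendering tests.
const_ctrl <- function(v_norm, dur = 5, rate = 100, azimuth = 0,
                       spread = 0) {
  n <- dur * rate + 1
  structure(
    data.frame(t = (0:(n - 1)) / rate, v_norm = v_norm, azimuth = azimuth,
               spread_ctl = spread),
    class = c("control_signal", "data.frame"),
    control_rate = rate, v_ref = 2
  )
}

# Interior index range excluding smoothing/derivative edge effects.
interior <- function(n, margin = 6) (margin + 1):(n - margin)

# Power spectrum of a mono render (positive frequencies).
render_spectrum <- function(audio) {
  x <- as.vector(audio$samples)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (0:(n - 1)) * audio$sample_rate / n
  keep <- f > 0 & f < audio$sample_rate / 2
  list(f = f[keep], p = p[keep])
}

# Amplitude envelope by moving-average rectification (window in seconds).
render_envelope <- function(audio, window = 0.005) {
  w <- max(3, round(window * audio$sample_rate))
  e <- stats::filter(abs(as.vector(audio$samples)), rep(1 / w, w), sides = 2)
  e[is.na(e)] <- 0
  as.numeric(e)
}
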