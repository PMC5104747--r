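# Offline rendering of the three filtered-noise sound models: velocity
# mappings, amplitude behaviour and 8-channel ring spatialization.

#' Parameters of the three filtered-noise sound models
#'
#' All three models filter white noise with a two-pole filter whose center
#' frequency and Q track movement velocity, and differ in their amplitude
#' behaviour:
#'
#' * **S1** — smooth, wind-like: resonant filter, f 50-1100 Hz,
#'   Q 1.8-4.0, band-limited random amplitude envelope at 3 Hz.
#' * **S2** — less smooth: resonant filter, f 100-900 Hz, Q 0.1-0.3,
#'   random amplitude envelope at 18 Hz.
#' * **S3** — choppy, clicking: band-pass filter, f 100-3000 Hz,
#'   Q 0.01-0.6, amplitude from non-linear ramps of 250 ms triggered
#'   every 50-800 ms depending on velocity.
#'
#' @param model_id `"S1"`, `"S2"` or `"S3"`.
#' @param ... Named overrides of any default field (e.g. `f_max`,
#'   `am_rate`, `trigger_decreasing`).
#' @return A list of class `sound_model_params` with fields `model_id`,
#'   `f_min`, `f_max`, `q_min`, `q_max`, `filter_kind`, `am_rate` (S1/S2),
#'   `ramp_length`, `ramp_curve`, `trigger_interval_min`,
#'   `trigger_interval_max`, `trigger_decreasing` (S3).
#' @export
sound_model_params <- function(model_id = c("S1", "S2", "S3"), ...) {
  model_id <- match.arg(model_id)
  p <- switch(model_id,
    S1 = list(model_id = "S1", f_min = 50, f_max = 1100,
              q_min = 1.8, q_max = 4.0, filter_kind = "resonant",
              am_rate = 3, ramp_length = NA_real_, ramp_curve = NA_real_,
              trigger_interval_min = NA_real_,
              trigger_interval_max = NA_real_, trigger_decreasing = NA),
    S2 = list(model_id = "S2", f_min = 100, f_max = 900,
              q_min = 0.1, q_max = 0.3, filter_kind = "resonant",
              am_rate = 18, ramp_length = NA_real_, ramp_curve = NA_real_,
              trigger_interval_min = NA_real_,
              trigger_interval_max = NA_real_, trigger_decreasing = NA),
    S3 = list(model_id = "S3", f_min = 100, f_max = 3000,
              q_min = 0.01, q_max = 0.6, filter_kind = "bandpass",
              am_rate = NA_real_, ramp_length = 0.25, ramp_curve = 4,
              trigger_interval_min = 0.05, trigger_interval_max = 0.8,
              trigger_decreasing = TRUE)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad) > 0) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  if (p$f_min >= p$f_max) stop("f_min must be < f_max")
  if (p$q_min > p$q_max) stop("q_min must be <= q_max")
  if (!is.na(p$trigger_interval_min) &&
      p$trigger_interval_min >= p$trigger_interval_max)
    stop("trigger_interval_min must be < trigger_interval_max")
  structure(p, class = "sound_model_params")
}

#' Control signal derived from a trajectory
#'
#' Resamples the movement onto a uniform control grid and extracts the
#' three quantities the sound models consume: normalized speed
#' (`clip(v / v_ref, 0, 1)`), azimuth from the room center
#' (`atan2(y, x)`, 0 on the positive x-axis), and a spread control equal
#' to the distance from the center normalized by the area half-diagonal.
#'
#' @param traj A `trajectory` in room-centered coordinates (meters).
#' @param control_rate Control update rate in Hz (default 100).
#' @param v_ref Speed mapped to full scale, m/s (default 2.0, fast child
#'   locomotion).
#' @param area Trackable area (width, height) in meters; sets the
#'   half-diagonal used to normalize the spread control.
#' @param smooth_frames,v_floor Passed to [kinematics()].
#' @return A data frame of class `control_signal` with columns `t`,
#'   `v_norm`, `azimuth`, `spread_ctl`; attributes record `control_rate`
#'   and `v_ref`.
#' @export
control_from_trajectory <- function(traj, control_rate = 100, v_ref = 2.0,
                                    area = c(4.66, 5.40),
                                    smooth_frames = 5, v_floor = 1e-3) {
  stopifnot(v_ref > 0, control_rate > 0)
  kin <- kinematics(traj, smooth_frames, v_floor)
  t0 <- traj$t[1]
  tc <- seq(0, duration(traj), by = 1 / control_rate)
  v <- approx(kin$t - t0, kin$v, xout = tc, rule = 2)$y
  x <- approx(kin$t - t0, kin$x, xout = tc, rule = 2)$y
  y <- approx(kin$t - t0, kin$y, xout = tc, rule = 2)$y
  half_diag <- sqrt(sum((area / 2)^2))
  out <- data.frame(
    t = tc,
    v_norm = pmin(pmax(v / v_ref, 0), 1),
    azimuth = atan2(y, x),
    spread_ctl = pmin(sqrt(x^2 + y^2) / half_diag, 1)
  )
  class(out) <- c("control_signal", "data.frame")
  attr(out, "control_rate") <- control_rate
  attr(out, "v_ref") <- v_ref
  out
}

#' Map normalized velocity to filter center frequency and Q
#'
#' Linear interpolation across the model's declared ranges:
#' `f_c = f_min + v_norm * (f_max - f_min)` and likewise for Q, so both
#' stay within the declared ranges for any `v_norm` in `[0, 1]`.
#'
#' @param ctrl A `control_signal` (or any data frame with `v_norm`).
#' @param params A [sound_model_params()].
#' @return A data frame with columns `f_c` (Hz) and `q`.
#' @export
map_control <- function(ctrl, params) {
  stopifnot(inherits(params, "sound_model_params"))
  v <- pmin(pmax(ctrl$v_norm, 0), 1)
  data.frame(f_c = params$f_min + v * (params$f_max - params$f_min),
             q = params$q_min + v * (params$q_max - params$q_min))
}

#' Logarithmic velocity-to-amplitude gain
#'
#' Maps the level `20*log10(v_norm)` affinely from `[floor_db, 0]` dB onto
#' `[0, 1]` amplitude, clipped; exactly zero where `v_norm = 0`, so no
#' sound is produced at rest.
#'
#' @param ctrl A `control_signal` (or any object with `v_norm`), or a bare
#'   numeric vector of normalized speeds.
#' @param floor_db Level treated as silence, dB (negative; default -60).
#' @return Gain vector in `[0, 1]`, non-decreasing in `v_norm`.
#' @export
amplitude_from_velocity <- function(ctrl, floor_db = -60) {
  stopifnot(floor_db < 0)
  v <- if (is.numeric(ctrl)) ctrl else ctrl$v_norm
  g <- numeric(length(v))
  pos <- v > 0
  g[pos] <- pmin(pmax(1 - 20 * log10(v[pos]) / floor_db, 0), 1)
  g
}

# Band-limited random envelope: uniform [0,1] targets drawn at am_rate,
# linearly interpolated between targets (the classic line-segment random
# signal generator).
random_envelope <- function(t, am_rate) {
  knots <- seq(0, max(t) + 1 / am_rate, by = 1 / am_rate)
  approx(knots, runif(length(knots)), xout = t)$y
}

# Triggered-ramp envelope for S3: a convex (slow-start) ramp of
# ramp_length seconds is launched at intervals linearly interpolated
# between trigger_interval_max (v_norm = 0) and trigger_interval_min
# (v_norm = 1); each trigger restarts the ramp, and the envelope is zero
# once a ramp has completed before the next trigger.
ramp_envelope <- function(t, v_norm, params) {
  dur <- max(t)
  tmin <- params$trigger_interval_min
  tmax <- params$trigger_interval_max
  triggers <- numeric(0)
  tt <- 0
  while (tt < dur) {
    triggers <- c(triggers, tt)
    v <- approx(t, v_norm, xout = tt, rule = 2)$y
    frac <- if (isTRUE(params$trigger_decreasing)) v else 1 - v
    tt <- tt + (tmax - frac * (tmax - tmin))
  }
  last <- triggers[findInterval(t, triggers)]
  phase <- (t - last) / params$ramp_length
  c_shape <- params$ramp_curve
  env <- (exp(c_shape * pmin(phase, 1)) - 1) / (exp(c_shape) - 1)
  env[phase > 1] <- 0
  env
}

# Per-sample biquad coefficients (normalized by a0) for the two filter
# realizations: "resonant" is the constant-0dB-peak band-pass form,
# "bandpass" the constant-skirt-gain form (standard audio-cookbook
# parameterization).
biquad_coefficients <- function(f_c, q, sr, kind) {
  w0 <- 2 * pi * pmin(f_c, sr / 2 * 0.95) / sr
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  b0 <- if (kind == "resonant") alpha else sin(w0) / 2
  list(b0 = b0 / a0, b1 = rep(0, length(w0)), b2 = -b0 / a0,
       a1 = -2 * cos(w0) / a0, a2 = (1 - alpha) / a0)
}

#' Render one sound model from a control signal
#'
#' Offline rendering chain: seeded white noise is shaped by a time-varying
#' two-pole filter whose center frequency and Q follow [map_control()]
#' (coefficients interpolated per sample), multiplied by the model's
#' amplitude envelope (band-limited random envelope for S1/S2, triggered
#' convex ramps for S3), and finally by the logarithmic velocity gain of
#' [amplitude_from_velocity()]. Where `v_norm` is zero the output is
#' exact digital silence. The output is peak-normalized to 0.99 only if
#' it would otherwise clip.
#'
#' @param ctrl A `control_signal` from [control_from_trajectory()].
#' @param params A [sound_model_params()].
#' @param sr Audio sample rate in Hz (>= 8000; default 44100).
#' @param seed Integer seed fixing the noise and envelope draws; identical
#'   inputs and seed give bit-identical renders.
#' @param floor_db Passed to [amplitude_from_velocity()].
#' @return A `rendered_audio` object (mono): list with `samples`
#'   (1 x n matrix in \[-1, 1\]), `sample_rate`, `channel_layout`, `meta`.
#' @export
render_model <- function(ctrl, params, sr = 44100, seed = 1,
                         floor_db = -60) {
  stopifnot(inherits(params, "sound_model_params"))
  if (sr < 8000) stop("invalid sample rate: need sr >= 8000")
  dur <- max(ctrl$t)
  n <- max(2, floor(dur * sr) + 1)
  ts <- (seq_len(n) - 1) / sr
  v <- approx(ctrl$t, ctrl$v_norm, xout = ts, rule = 2)$y
  maps <- map_control(data.frame(v_norm = v), params)
  co <- biquad_coefficients(maps$f_c, maps$q, sr, params$filter_kind)
  audio <- withr::with_seed(seed, {
    noise <- rnorm(n)
    filtered <- biquad_tv(noise, co$b0, co$b1, co$b2, co$a1, co$a2)
    env <- if (params$model_id %in% c("S1", "S2"))
      random_envelope(ts, params$am_rate)
    else
      ramp_envelope(ts, v, params)
    filtered * env
  })
  audio <- audio * amplitude_from_velocity(v, floor_db)
  audio[v == 0] <- 0
  peak <- max(abs(audio))
  if (peak > 0.99) audio <- audio * (0.99 / peak)
  rendered_audio(matrix(audio, nrow = 1), sr, "mono",
                 meta = list(model_id = params$model_id, seed = seed,
                             floor_db = floor_db,
                             control_rate = attr(ctrl, "control_rate"),
                             v_ref = attr(ctrl, "v_ref")))
}

#' Construct a rendered-audio buffer
#'
#' @param samples Numeric matrix, channels x samples, values in `[-1, 1]`.
#' @param sample_rate Sample rate, Hz.
#' @param channel_layout Label: `"mono"`, `"stereo"` or `"ring8"`.
#' @param meta Optional named list of render metadata (seed, mapping
#'   constants), written alongside audio files on request.
#' @return An object of class `rendered_audio`.
#' @export
rendered_audio <- function(samples, sample_rate,
                           channel_layout = c("mono", "stereo", "ring8"),
                           meta = list()) {
  channel_layout <- match.arg(channel_layout)
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (max(abs(samples)) > 1 + 1e-9) stop("samples exceed [-1, 1]")
  if (!nrow(samples) %in% c(1, 2, 8)) stop("channel count must be 1, 2 or 8")
  structure(list(samples = samples, sample_rate = sample_rate,
                 channel_layout = channel_layout, meta = meta),
            class = "rendered_audio")
}

#' @export
print.rendered_audio <- function(x, ...) {
  cat(sprintf("<rendered_audio> %d ch (%s), %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), x$channel_layout, ncol(x$samples),
              x$sample_rate, ncol(x$samples) / x$sample_rate))
  invisible(x)
}

# Ring panning gains for one control frame: constant-power pairwise
# panning between the two loudspeakers adjacent to the azimuth, blended
# toward the uniform distribution by the spread control and renormalized
# to unit total power.
ring_gains <- function(azimuth, spread, n_speakers) {
  sector <- 2 * pi / n_speakers
  az <- azimuth %% (2 * pi)
  s <- floor(az / sector)
  frac <- az / sector - s
  g <- numeric(n_speakers)
  g[s + 1] <- cos(frac * pi / 2)
  g[(s + 1) %% n_speakers + 1] <- g[(s + 1) %% n_speakers + 1] +
    sin(frac * pi / 2)
  u <- rep(1 / sqrt(n_speakers), n_speakers)
  g <- (1 - spread) * g + spread * u
  g / sqrt(sum(g^2))
}

#' Spatialize a mono render on a loudspeaker ring
#'
#' Places the moving sound source on a ring of `n_speakers` loudspeakers
#' at angles `2*pi*i/n`: per control frame, constant-power pairwise
#' panning between the two speakers adjacent to the azimuth; the spread
#' control widens the gains toward the uniform distribution (all channels
#' `1/sqrt(n)` at spread 1). Gains are interpolated per sample and
#' renormalized so the summed squared gain is 1 at every sample.
#'
#' @param mono A mono `rendered_audio`.
#' @param ctrl The `control_signal` providing `azimuth` and `spread_ctl`.
#' @param n_speakers Number of speakers on the ring (default 8).
#' @return An 8-channel (or `n_speakers`-channel) `rendered_audio`.
#' @export
spatialize <- function(mono, ctrl, n_speakers = 8) {
  stopifnot(inherits(mono, "rendered_audio"), nrow(mono$samples) == 1)
  n <- ncol(mono$samples)
  ts <- (seq_len(n) - 1) / mono$sample_rate
  frame_g <- vapply(seq_len(nrow(ctrl)), function(i)
    ring_gains(ctrl$azimuth[i], ctrl$spread_ctl[i], n_speakers),
    numeric(n_speakers))
  g <- vapply(seq_len(n_speakers), function(ch)
    approx(ctrl$t, frame_g[ch, ], xout = ts, rule = 2)$y,
    numeric(n))                       # n x n_speakers
  norm <- sqrt(rowSums(g^2))
  g <- g / norm
  samples <- t(g * as.vector(mono$samples))
  layout <- if (n_speakers == 8) "ring8" else "stereo"
  rendered_audio(samples, mono$sample_rate, layout, meta = mono$meta)
}

#' Constant-power stereo downmix of a ring render
#'
#' Pairs ring channels across the left/right axis with constant-power
#' weights, for desk listening of 8-channel renders.
#'
#' @param audio An 8-channel `rendered_audio`.
#' @return A stereo `rendered_audio`.
#' @export
downmix_stereo <- function(audio) {
  stopifnot(inherits(audio, "rendered_audio"), nrow(audio$samples) == 8)
  angles <- 2 * pi * (0:7) / 8
  # left weight by constant-power cosine panning across the y-axis
  wl <- (1 + sin(angles)) / 2
  left <- colSums(sqrt(wl) * audio$samples) / sqrt(8)
  right <- colSums(sqrt(1 - wl) * audio$samples) / sqrt(8)
  m <- rbind(left, right)
  peak <- max(abs(m))
  if (peak > 0.99) m <- m * (0.99 / peak)
  rendered_audio(m, audio$sample_rate, "stereo", meta = audio$meta)
}
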