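test_that("control signals normalize speed, azimuth and spread as
           documented", {
  still <- trajectory((0:999) / 180, rep(1, 1000), rep(0, 1000), 180)
  ctrl <- control_from_trajectory(still)
  expect_true(all(ctrl$v_norm == 0))
  # point on the positive x-axis: azimuth 0
  expect_true(all(abs(ctrl$azimuth) < 1e-9))
  # speed at v_ref maps to full scale
  line <- gen_trajectory("straight", mean_speed = 0.5, duration = 8)
  ctrl2 <- control_from_trajectory(line, v_ref = 0.5)
  mid <- ctrl2$v_norm[10:(nrow(ctrl2) - 10)]
  expect_equal(mid, rep(1, length(mid)), tolerance = 1e-6)
  expect_true(all(ctrl2$v_norm <= 1 & ctrl2$v_norm >= 0))
  expect_true(all(ctrl2$spread_ctl >= 0 & ctrl2$spread_ctl <= 1))
})

test_that("velocity maps linearly onto the declared filter ranges", {
  s1 <- sound_model_params("S1")
  m0 <- map_control(data.frame(v_norm = 0), s1)
  expect_equal(c(m0$f_c, m0$q), c(50, 1.8))
  m1 <- map_control(data.frame(v_norm = 1), s1)
  expect_equal(c(m1$f_c, m1$q), c(1100, 4.0))
  s3 <- sound_model_params("S3")
  mm <- map_control(data.frame(v_norm = 0.5), s3)
  expect_equal(c(mm$f_c, mm$q), c(1550, 0.305))
  # always inside the declared ranges, even for out-of-range input
  m_clip <- map_control(data.frame(v_norm = c(-0.5, 1.5)), s1)
  expect_true(all(m_clip$f_c >= 50 & m_clip$f_c <= 1100))
})

test_that("the velocity gain is zero at rest, one at full scale, and
           monotone", {
  expect_identical(amplitude_from_velocity(0), 0)
  expect_equal(amplitude_from_velocity(1), 1)
  v <- seq(0, 1, length.out = 200)
  g <- amplitude_from_velocity(v)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g <= 1))
  # the floor: -60 dB corresponds to v_norm = 1e-3
  expect_equal(amplitude_from_velocity(1e-3), 0)
})

test_that("all three models render exact digital silence at rest", {
  for (m in c("S1", "S2", "S3")) {
    a <- render_model(const_ctrl(0, dur = 2), sound_model_params(m),
                      sr = 16000, seed = 3)
    expect_true(all(a$samples == 0))
  }
})

test_that("renders are bit-identical under a fixed seed and differ
           across seeds", {
  ctrl <- const_ctrl(0.5, dur = 2)
  p <- sound_model_params("S2")
  a <- render_model(ctrl, p, sr = 16000, seed = 42)
  b <- render_model(ctrl, p, sr = 16000, seed = 42)
  expect_identical(a$samples, b$samples)
  c2 <- render_model(ctrl, p, sr = 16000, seed = 43)
  expect_false(identical(a$samples, c2$samples))
})

test_that("S1 spectra stay in the mapped band with a peak near the
           mapped center frequency and velocity-monotone centroid", {
  p <- sound_model_params("S1")
  cents <- vapply(c(0.2, 0.5, 0.8), function(v) {
    a <- render_model(const_ctrl(v, dur = 6), p, sr = 16000, seed = 11)
    s <- render_spectrum(a)
    f_c <- 50 + v * 1050
    q <- 1.8 + v * 2.2
    bw <- f_c / q
    if (v == 0.5) {
      ps <- stats::filter(s$p, rep(1 / 101, 101), sides = 2)
      peak <- s$f[which.max(ps)]
      expect_gt(peak, f_c - bw)
      expect_lt(peak, f_c + bw)
      inband <- sum(s$p[s$f >= max(0, 50 - bw) & s$f <= 1100 + bw]) /
        sum(s$p)
      expect_gte(inband, 0.9)
    }
    sum(s$f * s$p) / sum(s$p)
  }, numeric(1))
  expect_true(all(diff(cents) > 0))
})

test_that("S3 onset intervals follow the velocity-interpolated trigger
           law", {
  # at v_norm = 0.8 the interval law gives 0.05 + 0.2 * 0.75 = 0.2 s
  a <- render_model(const_ctrl(0.8, dur = 8), sound_model_params("S3"),
                    sr = 16000, seed = 5)
  env <- render_envelope(a)
  pk <- which(diff(sign(diff(env))) == -2) + 1
  pk <- pk[env[pk] > 0.3 * max(env)]
  pk <- pk[c(TRUE, diff(pk) > 0.05 * a$sample_rate)]
  ioi <- median(diff(pk)) / a$sample_rate
  expect_equal(ioi, 0.2, tolerance = 0.1)
})

test_that("amplitude-envelope roughness above 5 Hz orders S3 > S2 > S1
           at matched velocity", {
  rough <- vapply(c("S1", "S2", "S3"), function(m) {
    a <- render_model(const_ctrl(0.5, dur = 6), sound_model_params(m),
                      sr = 16000, seed = 9)
    e <- render_envelope(a, window = 0.01)
    e <- e[e > 0]
    e <- e / mean(e)
    n <- length(e)
    p <- Mod(stats::fft(e - mean(e)))^2
    f <- (0:(n - 1)) * a$sample_rate / n
    sum(p[f > 5 & f < 50]) / n
  }, numeric(1))
  expect_gt(rough[["S3"]], rough[["S2"]])
  expect_gt(rough[["S2"]], rough[["S1"]])
})

test_that("render rejects invalid sample rates and parameters", {
  expect_error(render_model(const_ctrl(0.5, dur = 1),
                            sound_model_params("S1"), sr = 4000),
               "sample rate")
  expect_error(sound_model_params("S1", f_min = 2000), "f_min")
  expect_error(sound_model_params("S4"))
  expect_error(sound_model_params("S1", bogus = 1), "unknown")
})

test_that("ring spatialization conserves power and honors the pan and
           spread laws", {
  g0 <- moveson:::ring_gains(0, 0, 8)
  expect_equal(g0, c(1, rep(0, 7)))
  gm <- moveson:::ring_gains(pi / 8, 0, 8)
  expect_equal(gm, c(1 / sqrt(2), 1 / sqrt(2), rep(0, 6)))
  gu <- moveson:::ring_gains(1.234, 1, 8)
  expect_equal(gu, rep(1 / sqrt(8), 8))
  # energy conservation per frame for arbitrary azimuth/spread
  gs <- withr::with_seed(2, {
    vapply(1:200, function(i)
      sum(moveson:::ring_gains(runif(1, -10, 10), runif(1), 8)^2),
      numeric(1))
  })
  expect_equal(gs, rep(1, 200), tolerance = 1e-6)

  # full pipeline: per-sample channel energy equals the mono energy
  tr <- gen_trajectory("smooth", duration = 3, seed = 3)
  ctrl <- control_from_trajectory(tr)
  mono <- render_model(ctrl, sound_model_params("S2"), sr = 16000,
                       seed = 2)
  multi <- spatialize(mono, ctrl)
  expect_equal(nrow(multi$samples), 8)
  expect_equal(colSums(multi$samples^2), as.vector(mono$samples)^2,
               tolerance = 1e-6)
})

test_that("WAV files round-trip with channel count preserved and only
           quantization error", {
  tr <- gen_trajectory("smooth", duration = 2, seed = 3)
  ctrl <- control_from_trajectory(tr)
  mono <- render_model(ctrl, sound_model_params("S1"), sr = 16000,
                       seed = 8)
  f <- withr::local_tempfile(fileext = ".wav")
  write_audio(mono, f)
  back <- read_audio(f)
  expect_equal(nrow(back$samples), 1)
  expect_equal(back$sample_rate, 16000)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(back$samples) - rms(mono$samples)), 1e-3)
  expect_lte(max(abs(back$samples)), 1)

  multi <- spatialize(mono, ctrl)
  f8 <- withr::local_tempfile(fileext = ".wav")
  write_audio(multi, f8, bits = 24,
              metadata_path = paste0(f8, ".json"))
  back8 <- read_audio(f8)
  expect_equal(nrow(back8$samples), 8)
  expect_lt(max(abs(back8$samples - multi$samples)), 1e-6)
  meta <- jsonlite::read_json(paste0(f8, ".json"))
  expect_equal(meta$model_id, "S1")
  expect_equal(meta$seed, 8)

  st <- downmix_stereo(multi)
  expect_equal(nrow(st$samples), 2)
  expect_error(write_audio(mono, ""), "path")
})
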