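test_that("speed and energy match closed forms on analytic paths", {
  line <- gen_trajectory("straight", mean_speed = 0.5, duration = 10)
  v <- speed(line)
  idx <- interior(length(v))
  expect_equal(v[idx], rep(0.5, length(idx)), tolerance = 1e-9)
  # EI = v^2 / 2 with unit mass
  ei <- energy_index(line)
  expect_equal(ei[idx], rep(0.125, length(idx)), tolerance = 1e-9)
  # stationary point
  still <- trajectory((0:99) / 180, rep(0.3, 100), rep(-0.2, 100), 180)
  expect_true(all(speed(still) == 0))
  expect_true(all(energy_index(still) == 0))
  # homogeneity: doubling speed quadruples EI
  line2 <- gen_trajectory("straight", mean_speed = 1.0, duration = 5)
  ei2 <- energy_index(line2)
  expect_equal(ei2[interior(length(ei2))],
               rep(4 * 0.125, length(interior(length(ei2)))),
               tolerance = 1e-8)
  # circle at angular rate omega: v = r * omega
  circ <- gen_trajectory("circle", mean_speed = 0.8, radius = 0.8,
                         duration = 10)
  vc <- speed(circ)
  expect_equal(vc[interior(length(vc))],
               rep(0.8, length(interior(length(vc)))), tolerance = 1e-3)
})

test_that("curvature is zero on lines, 1/r on circles, and peaked at
           square corners", {
  line <- gen_trajectory("straight", mean_speed = 0.5, duration = 10)
  k <- curvature(line)
  idx <- interior(length(k))
  expect_lt(max(abs(k[idx])), 1e-6)

  circ <- gen_trajectory("circle", mean_speed = 0.5, radius = 0.8,
                         duration = 10)
  kc <- curvature(circ)
  idxc <- interior(length(kc))
  expect_equal(abs(kc[idxc]), rep(1.25, length(idxc)), tolerance = 0.01)

  sq <- gen_trajectory("square", mean_speed = 0.5, duration = 16, side = 2)
  ks <- abs(curvature(sq))
  # corner curvature dwarfs edge curvature (edges are straight)
  corner_max <- max(ks, na.rm = TRUE)
  edge_typ <- quantile(ks, 0.5, na.rm = TRUE)
  expect_gt(corner_max, 10 * max(edge_typ, 1e-6))

  still <- trajectory((0:99) / 180, rep(0, 100), rep(0, 100), 180)
  expect_error(curvature(still), "no-motion")
})

test_that("curvature agrees with a circumscribed-circle oracle on a
           dense smooth curve", {
  tr <- powerlaw_fixture(duration = 4)
  k <- curvature(tr, smooth_frames = 1)
  k_oracle <- circumcircle_curvature(tr$x, tr$y)
  idx <- interior(length(k), margin = 10)
  rel <- abs(abs(k[idx]) - k_oracle[idx - 1]) / k_oracle[idx - 1]
  expect_lt(max(rel, na.rm = TRUE), 0.01)
})

test_that("pearson smoothness hits -1 on exact log-linear coupling and
           matches a brute-force window oracle", {
  tr <- powerlaw_fixture()
  si <- smoothness_index(tr)
  kin <- kinematics(tr)
  oracle <- si_window_oracle(kin)
  expect_equal(si$si, oracle, tolerance = 1e-12)
  # interior windows: near-perfect (negative) correlation
  ok <- si$si[2:(nrow(si) - 1)]
  ok <- ok[is.finite(ok)]
  expect_gte(length(ok), 200)
  expect_true(all(abs(ok) >= 0.99))
  expect_true(all(ok <= 0))
})

test_that("a window with exact negative log-linear dependence scores -1
           and degenerate windows are NA, with the simplified variant
           positive and unbounded", {
  lk <- seq(0.1, 1, length.out = 6)
  lv <- 2 - 0.5 * lk
  expect_equal(moveson:::window_statistic(lk, lv, "pearson"), -1)
  expect_true(is.na(moveson:::window_statistic(rep(1, 5), lv[1:5],
                                               "pearson")))
  simp <- moveson:::window_statistic(lk, lv, "simplified")
  expect_gt(simp, 0)
  # shrinking the spread inflates the simplified index without bound
  simp_small <- moveson:::window_statistic(lk / 10, lv / 10, "simplified")
  expect_gt(simp_small, simp)
})

test_that("independent jitter in the window logs yields weak mean
           correlation", {
  sis <- withr::with_seed(99, {
    vapply(1:200, function(i)
      moveson:::window_statistic(rnorm(5), rnorm(5), "pearson"),
      numeric(1))
  })
  expect_lt(mean(abs(sis)), 0.5)
})

test_that("directness index matches chord-over-path geometry", {
  line <- gen_trajectory("straight", mean_speed = 0.5, duration = 10)
  expect_equal(directness_index(line), 1, tolerance = 1e-9)
  expect_equal(directness_index(right_angle_fixture()), sqrt(2) / 2,
               tolerance = 1e-9)
  # closed loop: zero chord
  th <- seq(0, 2 * pi, length.out = 361)
  th[361] <- 2 * pi
  loop <- trajectory(seq_along(th) / 180, cos(th), sin(th), 180)
  loop$x[361] <- loop$x[1]; loop$y[361] <- loop$y[1]
  expect_equal(directness_index(loop), 0)
  still <- trajectory(c(0, 0.1), c(0, 0), c(0, 0), 10)
  expect_error(directness_index(still), "no-motion")
})

test_that("feature indices respect rigid-motion invariances", {
  tr <- gen_trajectory("smooth", duration = 6, seed = 21)
  rot <- function(traj, phi, dx = 0, dy = 0) {
    trajectory(traj$t,
               cos(phi) * traj$x - sin(phi) * traj$y + dx,
               sin(phi) * traj$x + cos(phi) * traj$y + dy,
               traj$rate, traj$marker_id)
  }
  moved <- rot(tr, 0.73, dx = 0.4, dy = -0.2)
  expect_equal(directness_index(moved), directness_index(tr),
               tolerance = 1e-9)
  expect_equal(energy_index(moved), energy_index(tr), tolerance = 1e-9)
  expect_equal(abs(curvature(moved)), abs(curvature(tr)), tolerance = 1e-6)
  # reflection flips the curvature sign, preserves magnitude
  refl <- trajectory(tr$t, tr$x, -tr$y, tr$rate)
  expect_equal(curvature(refl), -curvature(tr), tolerance = 1e-9)
})

test_that("directness never exceeds 1 on random seeded walks", {
  dis <- withr::with_seed(7, {
    vapply(1:1000, function(i) {
      n <- sample(10:60, 1)
      directness_index(trajectory((0:(n - 1)) / 30,
                                  cumsum(rnorm(n, sd = 0.05)),
                                  cumsum(rnorm(n, sd = 0.05)), 30))
    }, numeric(1))
  })
  expect_true(all(dis <= 1 + 1e-12))
  expect_true(all(dis >= 0))
})

test_that("per-observation summaries are deterministic and match a
           scripted mean-of-windows oracle", {
  tr <- gen_trajectory("smooth", duration = 8, seed = 31)
  a <- summarize_features(tr)
  b <- summarize_features(tr)
  expect_identical(a, b)
  kin <- kinematics(tr)
  si_oracle <- si_window_oracle(kin)
  si_ok <- si_oracle[is.finite(si_oracle)]
  expect_equal(a$SI_mean, mean(si_ok), tolerance = 1e-9)
  expect_equal(a$SI_absmean, mean(abs(si_ok)), tolerance = 1e-9)
  expect_equal(a$EI_mean, mean(0.5 * kin$v^2), tolerance = 1e-9)
  # constant-speed straight line: EI = v^2/2, SI windows degenerate, DI 1
  line <- gen_trajectory("straight", mean_speed = 0.5, duration = 10)
  s <- summarize_features(line)
  expect_equal(s$DI, 1, tolerance = 1e-9)
  expect_equal(s$EI_mean, 0.125, tolerance = 5e-3)
  # labels are carried through
  lab <- data.frame(segment_id = "s1", sound_model = "S2")
  expect_equal(summarize_features(tr, labels = lab)$sound_model, "S2")
})
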