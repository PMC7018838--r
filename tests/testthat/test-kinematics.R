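test_that("two-point velocity matches the pairwise-angle oracle", {
  set.seed(11)
  for (rep in 1:5) {
    v <- rand_directions(200, step_deg = runif(1, 0.1, 2))
    fs <- sample(c(60, 120, 250), 1)
    got <- two_point_velocity(v, fs)
    # oracle: angle via acos of the dot product, central window
    n <- nrow(v)
    dots <- rowSums(v[1:(n - 2), ] * v[3:n, ])
    oracle <- fs * acos(pmin(1, pmax(-1, dots))) / 2 * 180 / pi
    expect_equal(got[2:(n - 1)], oracle, tolerance = 1e-9)
    expect_true(all(got >= 0))
  }
})

test_that("uniform rotation is recovered exactly at interior samples", {
  fs <- 120
  ang <- (0:49) * 10 * pi / 180          # 10 deg per sample about z
  v <- cbind(cos(ang), sin(ang), 0)
  out <- two_point_velocity(v, fs)
  expect_equal(out[2:49], rep(fs * 10, 48), tolerance = 1e-6)
})

test_that("degenerate direction inputs are handled", {
  v <- matrix(rep(c(1, 0, 0), 10), ncol = 3, byrow = TRUE)
  expect_equal(two_point_velocity(v, 100), rep(0, 10))
  expect_error(two_point_velocity(v[1:2, ], 100), "at least 3")
})

test_that("small-angle components: plane constraint, 1% error at 14 deg, signs", {
  fs <- 120
  # rotation confined to the azimuthal plane -> elevation identically zero
  ang <- (0:20) * 7 * pi / 180           # 14 deg per central window
  v <- cbind(cos(ang), sin(ang), 0)
  sa <- suppressWarnings(small_angle_components(v, fs))
  expect_equal(sa$el, rep(0, 21), tolerance = 1e-12)
  # sine-for-angle approximation is 1% low at a 14 degree step
  exact <- fs * 14 / 2
  rel_err <- 1 - abs(sa$az[10]) / exact
  expect_equal(rel_err, 1 - sin(14 * pi / 180) / (14 * pi / 180),
               tolerance = 1e-6)
  expect_equal(round(100 * rel_err), 1)
  # counterclockwise viewed along +z is negative (clockwise positive)
  expect_lt(sa$az[10], 0)
  # mirrored trace flips the azimuthal sign
  vm <- v; vm[, 2] <- -vm[, 2]
  sam <- suppressWarnings(small_angle_components(vm, fs))
  expect_equal(sam$az, -sa$az, tolerance = 1e-12)
})

test_that("signed components never exceed the magnitude", {
  set.seed(12)
  v <- rand_directions(300, 1.5)
  fs <- 120
  mag <- two_point_velocity(v, fs)
  sa <- small_angle_components(v, fs)
  expect_true(all(abs(sa$az) <= mag * (1 + 1e-6) + 1e-9))
  expect_true(all(abs(sa$el) <= mag * (1 + 1e-6) + 1e-9))
})

test_that("anti-alias filter: DC gain, stopband attenuation, zero phase", {
  fs <- 120
  t <- (0:1199) / fs
  expect_equal(antialias_lowpass(rep(3.3, 600), fs), rep(3.3, 600),
               tolerance = 1e-3)
  x <- sin(2 * pi * 10 * t) + sin(2 * pi * 59.5 * t)
  y <- antialias_lowpass(x, fs)
  amp <- function(v, f) abs(fft(v)[round(f * length(v) / fs) + 1])
  expect_gt(amp(y, 10) / amp(x, 10), 0.99)           # passband gain ~1
  expect_lt(20 * log10(amp(y, 59.5) / amp(x, 59.5)), -20)
  # zero-phase: cross-correlation with a bandlimited input peaks at lag 0
  set.seed(13)
  n <- 2048
  Z <- fft(rnorm(n))
  k <- round(n * 20 / fs)
  Z[k:(n - k)] <- 0
  xb <- Re(fft(Z, inverse = TRUE)) / n
  yb <- antialias_lowpass(xb, fs)
  cc <- ccf(yb, xb, lag.max = 5, plot = FALSE)
  expect_identical(as.integer(cc$lag[which.max(cc$acf)]), 0L)
})

test_that("anti-alias filter refuses short series unless padded", {
  expect_error(antialias_lowpass(rnorm(50), 120), "pad = TRUE")
  expect_silent(antialias_lowpass(rnorm(50), 120, pad = TRUE))
})

test_that("bilateral filter preserves saccade peaks where a Gaussian does not", {
  fs <- 120
  tt <- (0:599) / fs
  v <- 5 + 395 * exp(-((tt - 2.5) / 0.009)^2)        # ~30 ms, 400 deg/s peak
  bi <- bilateral_smooth(v, fs, filter_config())
  ga <- bilateral_smooth(v, fs, filter_config(bilateral_sigma_r = 1e9))
  expect_gte(max(bi) / max(v), 0.95)
  expect_lt(max(ga) / max(v), 0.90)
})

test_that("bilateral filter: exact on constants, bounded, noise-reducing", {
  fs <- 120
  expect_equal(bilateral_smooth(rep(7.7, 100), fs), rep(7.7, 100))
  set.seed(14)
  x <- 10 + rnorm(600, sd = 2)                       # sigma << sigma_r
  y <- bilateral_smooth(x, fs)
  expect_lte(var(y), var(x))
  expect_true(all(y >= min(x) - 1e-12 & y <= max(x) + 1e-12))
})

test_that("gaze_in_world matches a rotation-matrix oracle and VOR identity", {
  set.seed(15)
  n <- 100
  q <- rand_quats(n)
  v <- rand_directions(n, 5)
  giw <- gaze_in_world(v, q)
  oracle <- t(vapply(seq_len(n), function(i) rotmat_from_quat(q[i, ]) %*% v[i, ],
                     numeric(3)))
  expect_equal(giw, oracle, tolerance = 1e-9, ignore_attr = TRUE)
  # identity head: GiW = EiH
  expect_equal(gaze_in_world(v, identity_quats(n)), v, tolerance = 1e-12,
               ignore_attr = TRUE)
  # perfect VOR: head yaw +theta, eye yaw -theta -> constant gaze
  theta <- seq(0, 30, length.out = 200)
  head <- quat_from_euler(theta, theta * 0)
  eih <- cbind(cos(-theta * pi / 180), sin(-theta * pi / 180), 0)
  g <- gaze_in_world(eih, head)
  expect_lt(max(two_point_velocity(g, 120)), 1e-6)
})

test_that("quaternion slerp interpolates the geodesic", {
  q <- rbind(c(1, 0, 0, 0), quat_from_axis_angle(c(0, 0, 1), pi / 2))
  out <- quat_slerp(q, c(0, 1), c(0, 0.5, 1))
  expect_equal(out[1, ], c(1, 0, 0, 0), tolerance = 1e-12)
  expect_equal(out[3, ], as.numeric(q[2, ]), tolerance = 1e-12)
  expect_equal(out[2, ], as.numeric(quat_from_axis_angle(c(0, 0, 1), pi / 4)),
               tolerance = 1e-12)
})

test_that("velocity pipeline masks low confidence and aligns six channels", {
  tr <- rand_trace(500, seed = 16)
  tr$confidence[100:104] <- 0.2
  vel <- velocity_pipeline(tr)
  expect_false(any(vel$mask[100:104]))
  expect_true(all(vel$mask[setdiff(1:500, 100:104)]))
  for (ch in c("we", "wh", "we_az", "wh_az", "we_el", "wh_el"))
    expect_length(vel[[ch]], 500)
  expect_identical(vel$timestamps, tr$timestamps)
  expect_true(all(vel$we >= 0) && all(vel$wh >= 0))
})

test_that("pure-VOR fixation: eye speed tracks head speed, gaze speed near zero", {
  spec <- synthetic_spec(duration = 20,
                         mix = c(fix_stationary = 0, fix_vor = 1, pur = 0,
                                 sac = 0, blink = 0),
                         dropout_rate = 0, seed = 17)
  rec <- generate_recording(spec)
  vel <- velocity_pipeline(rec$trace)
  sel <- vel$mask & vel$wh > 5
  expect_equal(median(vel$we[sel] / vel$wh[sel]), 1, tolerance = 0.05)
  giw <- gaze_in_world(rec$trace$eih, rec$trace$head)
  gvel <- two_point_velocity(giw, rec$trace$fs)
  expect_lt(median(gvel), 1)     # residual tremor only
})

test_that("per-sample displacement bound at physiological extremes", {
  expect_equal(per_sample_displacement(900, 120), 7.5)
  expect_lte(per_sample_displacement(900, 120), 8)
})
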