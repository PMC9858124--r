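test_that("wrist angle inverts the generative composition exactly", {
  # hand = forearm x rot(flexion axis, 17 deg) under arbitrary forearm pose
  set.seed(4)
  n <- 100
  fore <- quat_normalize(matrix(rnorm(4 * n), n, 4))
  hand <- quat_multiply(fore, quat_from_axis_angle(c(1, 0, 0), rep(17, n)))
  qs <- structure(list(hand_q = hand, forearm_q = fore, fs = 50,
                       subject_id = "S", trial = 1L,
                       design_label = "tremor", params = NULL),
                  class = "quaternion_stream")
  ang <- quaternions_to_wrist_angle(qs)
  expect_equal(ang$angle, rep(17, n), tolerance = 1e-9)

  # synthetic tremor round trip: injected sinusoid recovered to < 1e-6 deg
  cfg <- clean_kin_config(f = 6, amp = 5)
  qs2 <- simulate_kinematics(cfg, "tremor", "P01")
  rec <- quaternions_to_wrist_angle(qs2)$angle
  t <- (seq_along(rec) - 1) / 50
  # fit phase/amplitude of a 6 Hz sinusoid by linear regression (oracle)
  fit <- lm(rec ~ sin(2 * pi * 6 * t) + cos(2 * pi * 6 * t) - 1)
  expect_lt(max(abs(rec - fitted(fit))), 1e-6)
  expect_equal(sqrt(sum(coef(fit)^2)), 5, tolerance = 1e-9)
})

test_that("tremor band-pass rejects DC, passes 6 Hz with zero lag", {
  dc <- bandpass_tremor(rep(5, 300), fs = 50)
  expect_lt(max(abs(dc)), 5 * 1e-8)

  t <- (0:499) / 50
  s6 <- sin(2 * pi * 6 * t)
  y <- bandpass_tremor(s6, fs = 50)
  cc <- ccf(y, s6, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_gt(fft_amplitude(y, 6, 50), 0.9)
})

test_that("band-pass separates tremor from postural components", {
  t <- (0:499) / 50
  mix <- sin(2 * pi * 1 * t) + sin(2 * pi * 6 * t)
  y <- bandpass_tremor(mix, fs = 50)
  expect_gt(fft_amplitude(y, 6, 50), 0.90)       # tremor retained
  expect_lt(fft_amplitude(y, 1, 50), 0.1)        # drift attenuated >= 10x
})

test_that("zero-lag filter commutes with time reversal", {
  set.seed(8)
  x <- rnorm(400)
  fwd <- bandpass_tremor(x, fs = 50)
  revd <- bandpass_tremor(rev(x), fs = 50)
  expect_equal(rev(revd), fwd, tolerance = 1e-8)
})

test_that("filtering errors on too-short input and low rates", {
  expect_error(bandpass_tremor(rnorm(10), fs = 50), "short")
  expect_error(bandpass_tremor(rnorm(100), fs = 15), "twice")
})

test_that("windowing: counts, remainder handling, provenance", {
  cfg <- clean_kin_config()
  ang <- quaternions_to_wrist_angle(simulate_kinematics(cfg, "tremor", "P01"))
  ws <- segment_windows(ang)
  expect_equal(nrow(ws$x), 60)           # 60 s at 50 Hz -> 60 windows
  expect_equal(ws$window_len, 50)
  expect_true(all((ws$start - 1) %% 50 == 0))
  expect_equal(sum(nrow(ws$x) * ws$window_len), 3000)

  ws2 <- segment_windows(rnorm(75), fs = 50)
  expect_equal(nrow(ws2$x), 1)           # 25-sample remainder dropped
  expect_warning(segment_windows(rnorm(20), fs = 50), "shorter")
  # window count conservation with overlap = 0
  expect_lte(nrow(ws$x) * ws$window_len, length(ang$angle))
})

test_that("global [0,1] normalization is the exact affine map", {
  ws <- segment_windows(c(-30, 0, 30, seq(-30, 30, length.out = 97)),
                        fs = 50)
  nrm <- normalize_global(ws)
  expect_equal(range(nrm$x), c(0, 1))
  expect_equal(nrm$x[1, 2], 0.5)  # 0 degrees maps to the midpoint
  # idempotence on an already-[0,1] set
  again <- normalize_global(nrm)
  expect_equal(again$x, nrm$x, tolerance = 1e-12)
  # stored stats applied to wider data exceed [0,1]: no clipping
  wider <- segment_windows(seq(-60, 60, length.out = 100), fs = 50)
  mapped <- normalize_global(wider, stats = nrm$norm_stats)
  expect_gt(max(mapped$x), 1)
  expect_lt(min(mapped$x), 0)
  # degenerate range errors
  expect_error(normalize_global(segment_windows(rep(1, 100), fs = 50)),
               "degenerate")
})
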