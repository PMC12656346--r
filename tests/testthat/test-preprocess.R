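test_that("body-scale normalization fixes shoulder width at 1 and is scale invariant", {
  seq <- make_test_seq(units = "pixels",
                       x_over = list(left_shoulder = -50, right_shoulder = 50),
                       y_over = list(left_shoulder = 80, right_shoulder = 80))
  norm <- normalize_body_scale(seq)
  expect_identical(norm$units, "body_scale")
  expect_equal(unname(norm$x[1, "right_shoulder"] - norm$x[1, "left_shoulder"]),
               1, tolerance = 1e-12)

  doubled <- seq
  doubled$x <- seq$x * 2; doubled$y <- seq$y * 2
  expect_equal(normalize_body_scale(doubled)$x, norm$x, tolerance = 1e-9)

  # idempotent up to numerical noise
  norm2 <- normalize_body_scale(norm)
  expect_equal(norm2$x, norm$x, tolerance = 1e-9)
})

test_that("overlapping shoulders raise a degenerate-skeleton error", {
  seq <- make_test_seq(units = "pixels",
                       x_over = list(left_shoulder = 10, right_shoulder = 10),
                       y_over = list(left_shoulder = 5, right_shoulder = 5))
  expect_error(normalize_body_scale(seq), "degenerate")
})

test_that("moving average: identity, constancy, impulse response, range containment", {
  tr <- trajectory(c(0, 0, 0, 1, 0, 0, 0), 0, 1 / 30)
  expect_equal(smooth_moving_average(tr, 1)$values, tr$values)
  expect_equal(smooth_moving_average(trajectory(rep(4, 9), 0, 1), 5)$values,
               rep(4, 9))
  sm <- smooth_moving_average(tr, 3)
  expect_equal(sm$values, c(0, 0, 1 / 3, 1 / 3, 1 / 3, 0, 0))
  expect_error(smooth_moving_average(tr, 4), "odd")

  set.seed(11)
  for (i in 1:20) {
    v <- rnorm(50)
    for (w in c(3, 5, 9)) {
      s <- smooth_moving_average(trajectory(v, 0, 1), w)$values
      expect_gte(min(s), min(v))
      expect_lte(max(s), max(v))
    }
  }
})

test_that("uniform resampling reproduces linear ramps and constants exactly", {
  ramp <- trajectory(seq(0, 5, length.out = 31), 0, 1 / 30)
  for (n in c(7, 31, 113)) {
    rs <- resample_uniform(ramp, n)
    expect_equal(rs$values, seq(0, 5, length.out = n), tolerance = 1e-9)
  }
  const <- trajectory(rep(2.5, 10), 0, 0.1)
  expect_equal(resample_uniform(const, 50)$values, rep(2.5, 50))
  # identity at the original sampling on an already-uniform grid
  expect_equal(resample_uniform(ramp, 31)$values, ramp$values,
               tolerance = 1e-9)
})

test_that("cubic resampling of a sine beats the linear-interpolation error", {
  t30 <- seq(0, 1, by = 1 / 30)
  tr <- trajectory(sin(2 * pi * t30), 0, 1 / 30)
  t120 <- seq(0, 1, length.out = 121)
  cubic <- resample_uniform(tr, 121, "cubic")$values
  linear <- resample_uniform(tr, 121, "linear")$values
  truth <- sin(2 * pi * t120)
  expect_lt(max(abs(cubic - truth)), max(abs(linear - truth)))
})

test_that("swing-window cropping finds the onset and clamps to clip bounds", {
  # default-style swing with a 5 s address: onset ~ 5 s -> window [3, 6]
  long <- generate_swing(swing_style(
    phase_durations = c(5, 0.3, 0.25, 0.15, 0.25, 0.3, 0.85),
    noise_sigma = 0, seed = 2))
  cropped <- crop_swing_window(normalize_body_scale(long$sequence))
  expect_equal(cropped$time[1], 3, tolerance = 0.1)
  expect_equal(cropped$time[length(cropped$time)], 6, tolerance = 0.1)

  # early onset: window clamped to the clip start
  early <- generate_swing(swing_style(
    phase_durations = c(0.5, 0.3, 0.25, 0.15, 0.25, 0.3, 2.0),
    noise_sigma = 0, seed = 3))
  cr <- crop_swing_window(normalize_body_scale(early$sequence))
  expect_equal(cr$time[1], 0)

  still <- make_test_seq(n = 120)
  expect_error(crop_swing_window(still), "no swing")
})

test_that("address alignment centers mid-hips and is translation invariant", {
  a <- normalize_body_scale(cached_clip(seed = 31)$sequence)
  b <- a
  b$x <- b$x + 1.7; b$y <- b$y - 0.4
  al <- align_address(a, b)
  expect_equal(al[[1]]$x, al[[2]]$x, tolerance = 1e-9)
  expect_equal(al[[1]]$y, al[[2]]$y, tolerance = 1e-9)

  other <- normalize_body_scale(cached_clip(seed = 32)$sequence)
  al2 <- align_address(a, other)
  for (s in al2) {
    idx <- seq_len(max(2, ceiling(length(s$time) * 0.1)))
    expect_equal(mean((s$x[idx, "left_hip"] + s$x[idx, "right_hip"]) / 2), 0,
                 tolerance = 1e-9)
    expect_equal(mean((s$y[idx, "left_hip"] + s$y[idx, "right_hip"]) / 2), 0,
                 tolerance = 1e-9)
  }
  # self-alignment returns identical outputs
  self <- align_address(a, a)
  expect_equal(self[[1]], self[[2]])
})

test_that("the preprocessing pipeline is deterministic", {
  cl <- cached_clip(seed = 33)
  p1 <- prepare_swing(cl$sequence)
  p2 <- prepare_swing(cl$sequence)
  expect_identical(p1$seq$x, p2$seq$x)
  expect_identical(p1$seg$boundaries, p2$seg$boundaries)
})
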