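test_that("spine angle matches hand-computed postures", {
  up <- make_test_seq(n = 5,
                      x_over = list(left_hip = 0.3, right_hip = 0.7,
                                    left_shoulder = 0.3, right_shoulder = 0.7),
                      y_over = list(left_hip = 0.9, right_hip = 0.9,
                                    left_shoulder = 0.4, right_shoulder = 0.4))
  expect_equal(spine_angle_trajectory(up)$values, rep(0, 5), tolerance = 1e-9)

  tilt <- make_test_seq(n = 5,
                        x_over = list(left_shoulder = 0.8, right_shoulder = 1.2),
                        y_over = list(left_shoulder = 0.5, right_shoulder = 0.5))
  # mid-hip (0, 1.5) -> mid-shoulder (1, 0.5): equal x and upward offsets
  expect_equal(spine_angle_trajectory(tilt)$values, rep(45, 5),
               tolerance = 1e-9)

  flat <- make_test_seq(n = 5,
                        x_over = list(left_shoulder = 0.6, right_shoulder = 1.4),
                        y_over = list(left_shoulder = 1.5, right_shoulder = 1.5))
  expect_equal(spine_angle_trajectory(flat)$values, rep(90, 5),
               tolerance = 1e-9)

  degen <- make_test_seq(n = 5,
                         x_over = list(left_shoulder = -0.35,
                                       right_shoulder = 0.35),
                         y_over = list(left_shoulder = 1.5,
                                       right_shoulder = 1.5))
  expect_error(spine_angle_trajectory(degen), "degenerate")
})

test_that("spine angle is invariant to translation and uniform scaling", {
  cl <- cached_clip(seed = 71)
  ref <- spine_angle_trajectory(cl$sequence)$values
  moved <- cl$sequence
  moved$x <- moved$x * 2.5 + 120; moved$y <- moved$y * 2.5 - 40
  expect_equal(spine_angle_trajectory(moved)$values, ref, tolerance = 1e-9)
})

test_that("spine-angle delta: identity, constant offset, symmetry", {
  a <- generate_swing(swing_style(noise_sigma = 0, spine_sway_amp = 0, seed = 1))
  expect_equal(spine_angle_delta(a$sequence, a$sequence), 0, tolerance = 1e-12)

  b <- generate_swing(swing_style(noise_sigma = 0, spine_sway_amp = 0,
                                  spine_lean = 22, seed = 1))
  d_ab <- spine_angle_delta(a$sequence, b$sequence)
  expect_equal(d_ab, 10, tolerance = 0.2)
  expect_equal(spine_angle_delta(b$sequence, a$sequence), d_ab,
               tolerance = 1e-12)
})

test_that("spine-angle delta grows with sway amplitude", {
  stable <- generate_swing(swing_style(spine_sway_amp = 2, seed = 5))
  deltas <- sapply(c(5, 10, 20), function(amp)
    spine_angle_delta(stable$sequence,
                      generate_swing(swing_style(spine_sway_amp = amp,
                                                 seed = 5))$sequence))
  expect_true(all(deltas > 0))
  expect_true(all(diff(deltas) > 0))
})

test_that("matched-frame analysis labels follow the swing-plane offset", {
  pro <- generate_swing(swing_style(plane_offset = -0.08, seed = 81))
  ama <- generate_swing(swing_style(plane_offset = +0.08, seed = 82))
  m_pro <- matched_frame_analysis(pro$sequence)
  m_ama <- matched_frame_analysis(ama$sequence)
  expect_identical(m_pro$label, "downswing_lower")
  expect_identical(m_ama$label, "backswing_lower")
  for (m in list(m_pro, m_ama)) {
    expect_lt(m$backswing_frame, m$top_frame)
    expect_lt(m$top_frame, m$downswing_frame)
    expect_lt(abs(m$backswing_y - m$reference_height), 0.1)
    expect_lt(abs(m$downswing_y - m$reference_height), 0.1)
  }

  # a symmetric noiseless swing has no plane separation
  sym <- generate_swing(swing_style(plane_offset = 0, noise_sigma = 0,
                                    seed = 83))
  expect_identical(matched_frame_analysis(sym$sequence)$label, "indeterminate")

  # flipping the offset sign flips the label (fixed seed)
  flip_a <- generate_swing(swing_style(plane_offset = -0.06, seed = 84))
  flip_b <- generate_swing(swing_style(plane_offset = +0.06, seed = 84))
  expect_identical(matched_frame_analysis(flip_a$sequence)$label,
                   "downswing_lower")
  expect_identical(matched_frame_analysis(flip_b$sequence)$label,
                   "backswing_lower")
})

test_that("an unreachable reference height raises a no-match error", {
  cl <- cached_clip(seed = 85)
  expect_error(matched_frame_analysis(cl$sequence, reference = 5),
               "never approached")
})
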