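# small configs reused throughout: no smoothing, short clips
cfg_raw <- similarity_config(preprocess = preprocess_config(smoothing_window = 1))

test_that("area dissimilarity matches closed forms", {
  g <- seq(0, 1, length.out = 101)
  tr <- function(v) trajectory(v, 0, g[2])
  expect_identical(trajectory_area_dissimilarity(tr(sin(g)), tr(sin(g))), 0)
  expect_equal(trajectory_area_dissimilarity(tr(rep(0.3, 101)),
                                             tr(rep(0.8, 101))), 0.5)
  gg <- seq(0, 1, length.out = 10001)
  expect_equal(trajectory_area_dissimilarity(
    trajectory(sin(2 * pi * gg), 0, gg[2]),
    trajectory(rep(0, 10001), 0, gg[2])), 2 / pi, tolerance = 1e-6)
  expect_error(trajectory_area_dissimilarity(tr(g), trajectory(g, 0, 1)),
               "grid")
})

test_that("area dissimilarity has L1 metric structure", {
  set.seed(7)
  g <- seq(0, 1, length.out = 60)
  for (i in 1:200) {
    x <- trajectory(rnorm(60), 0, g[2])
    y <- trajectory(rnorm(60), 0, g[2])
    z <- trajectory(rnorm(60), 0, g[2])
    dxy <- trajectory_area_dissimilarity(x, y)
    dyx <- trajectory_area_dissimilarity(y, x)
    dxz <- trajectory_area_dissimilarity(x, z)
    dzy <- trajectory_area_dissimilarity(z, y)
    expect_gte(dxy, 0)
    expect_identical(dxy, dyx)
    expect_lte(dxy, dxz + dzy + 1e-12)
  }
})

test_that("the similarity map is calibrated and monotone", {
  expect_identical(dissimilarity_to_similarity(0), 1)
  expect_equal(dissimilarity_to_similarity(2.5, lambda = 2.5), 0.5)
  s <- dissimilarity_to_similarity(seq(0, 2, by = 0.1), lambda = 1)
  expect_true(all(diff(s) < 0))
  expect_error(dissimilarity_to_similarity(-0.1), "non-negative")
})

test_that("phase dissimilarity: identity, uniform weights, constant offset", {
  cl <- cached_clip(seed = 41)
  p <- prepare_swing(cl$sequence)
  slices <- phase_slices(p$seq, p$seg)
  sc <- phase_dissimilarity(slices$impact, slices$impact)
  expect_true(all(sc$per_joint_DS == 0))
  expect_identical(sc$similarity, 1)

  shifted <- slices$impact
  shifted$x[, "left_wrist"] <- shifted$x[, "left_wrist"] + 0.2
  sc2 <- phase_dissimilarity(slices$impact, shifted)
  expect_equal(unname(sc2$per_joint_DS["left_wrist"]), 0.1, tolerance = 1e-9)
  expect_true(all(sc2$per_joint_DS[setdiff(names(sc2$per_joint_DS),
                                           "left_wrist")] < 1e-12))
  expect_equal(sc2$weighted_DS, mean(sc2$per_joint_DS))  # uniform weights

  wcfg <- similarity_config(weights = "biomech")
  sc3 <- phase_dissimilarity(slices$impact, shifted, wcfg)
  w <- wcfg$weights
  expect_equal(sc3$weighted_DS,
               sum(w * sc3$per_joint_DS) / sum(w))
  expect_gt(sc3$weighted_DS, sc2$weighted_DS)  # wrists upweighted
})

test_that("dmsm_compare: identity, style discrimination, joint checks", {
  a1 <- cached_clip(seed = 51)
  rep_self <- dmsm_compare(a1$sequence, a1$sequence)
  expect_identical(rep_self$overall_similarity, 1)
  expect_identical(rep_self$overall_DS, 0)
  expect_length(rep_self$phase_scores, 7L)
  expect_identical(unname(vapply(rep_self$phase_scores, `[[`, character(1),
                                 "phase_name")), phase_names)

  a2 <- generate_swing(swing_style(seed = 52))
  b1 <- generate_swing(swing_style(arc_radius = 1.4, top_height = -1.25,
                                   plane_offset = 0.08, seed = 53))
  within_ds <- dmsm_compare(a1$sequence, a2$sequence)$overall_DS
  cross_ds <- dmsm_compare(a1$sequence, b1$sequence)$overall_DS
  expect_lt(within_ds, cross_ds)

  no_elbows <- make_test_seq(n = 90)
  no_elbows$x <- no_elbows$x[, setdiff(colnames(no_elbows$x), "left_elbow")]
  no_elbows$y <- no_elbows$y[, setdiff(colnames(no_elbows$y), "left_elbow")]
  expect_error(dmsm_compare(a1$sequence, no_elbows), "left_elbow")
})

test_that("DTW: diagonal identity, forced paths, and the worked example", {
  v <- c(0.1, 0.5, 0.2, 0.9)
  al <- dtw_align(v, v)
  expect_identical(al$cost, 0)
  expect_equal(al$path, cbind(1:4, 1:4))

  ex <- dtw_align(c(0, 0, 1), c(0, 1))
  expect_identical(ex$cost, 0)
  expect_equal(ex$path, cbind(c(1L, 2L, 3L), c(1L, 1L, 2L)))

  one <- dtw_align(3, c(1, 2, 5))
  expect_equal(one$cost, sum(abs(3 - c(1, 2, 5))))
  expect_equal(one$path, cbind(c(1L, 1L, 1L), 1:3))

  expect_error(dtw_align(numeric(0), 1:3), "empty")
})

test_that("DP cost equals the exhaustive monotone-path minimum", {
  set.seed(17)
  for (trial in 1:100) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    a <- sample(0:9, n, replace = TRUE)
    b <- sample(0:9, m, replace = TRUE)
    expect_equal(dtw_align(a, b)$cost, dtw_brute_force(a, b),
                 tolerance = 1e-12)
  }
})

test_that("DTW cosine similarity: identity, antiparallel motion, determinism", {
  cl <- cached_clip(seed = 61)
  expect_equal(dtw_cosine_similarity(cl$sequence, cl$sequence), 1,
               tolerance = 1e-9)

  # single moving joint, monotone path; time-reversal flips every motion vector
  n <- 40
  fwd <- make_test_seq(n = n, x_over = list(left_wrist = seq(-0.4, 1, length.out = n)))
  rev <- make_test_seq(n = n, x_over = list(left_wrist = seq(1, -0.4, length.out = n)))
  expect_equal(dtw_cosine_similarity(fwd, rev, cfg_raw), -1, tolerance = 1e-9)

  other <- cached_clip(seed = 62)
  s1 <- dtw_cosine_similarity(cl$sequence, other$sequence)
  s2 <- dtw_cosine_similarity(cl$sequence, other$sequence)
  expect_identical(s1, s2)
  expect_true(s1 >= -1 && s1 <= 1)

  static <- make_test_seq(n = 20)
  expect_error(dtw_cosine_similarity(static, fwd, cfg_raw), "static")
})

test_that("Euclidean baseline: identity, constant offset, symmetry", {
  cl <- cached_clip(seed = 63)
  expect_equal(as.numeric(euclidean_similarity(cl$sequence, cl$sequence)), 1)

  a <- normalize_body_scale(cl$sequence)
  b <- a
  d <- c(0.3, -0.4)  # norm 0.5
  b$x <- b$x + d[1]; b$y <- b$y + d[2]
  s <- euclidean_similarity(a, b, cfg_raw)
  expect_equal(attr(s, "DS"), 0.5, tolerance = 1e-9)

  other <- normalize_body_scale(cached_clip(seed = 64)$sequence)
  expect_equal(as.numeric(euclidean_similarity(a, other, cfg_raw)),
               as.numeric(euclidean_similarity(other, a, cfg_raw)),
               tolerance = 1e-12)
})

test_that("phase-wise Pearson correlation: identity, negation, degenerate input", {
  n <- 50
  tt <- seq(0, 1, length.out = n)
  wobble <- list(left_wrist = sin(2 * pi * tt), right_wrist = cos(2 * pi * tt),
                 left_elbow = tt^2, right_elbow = sqrt(tt),
                 left_shoulder = sin(4 * pi * tt) - 0.5,
                 right_shoulder = cos(4 * pi * tt) + 0.5,
                 left_hip = tt - 0.35, right_hip = 0.35 - tt)
  a <- make_test_seq(n = n, x_over = wobble, y_over = wobble)
  expect_equal(pearson_phase_correlation(a, a), 1, tolerance = 1e-9)

  neg <- a
  neg$x <- sweep(-a$x, 2, -2 * colMeans(a$x))  # reflect about the mean
  neg$y <- sweep(-a$y, 2, -2 * colMeans(a$y))
  expect_equal(pearson_phase_correlation(a, neg), -1, tolerance = 1e-9)

  flat <- make_test_seq(n = n)
  expect_error(suppressWarnings(pearson_phase_correlation(flat, flat)),
               "constant")
})

test_that("joint-angle baseline: identity, right-angle closed form, invariance", {
  cl <- cached_clip(seed = 65)
  expect_equal(as.numeric(joint_angle_similarity(cl$sequence, cl$sequence)), 1)

  # straight arms (180 deg at both elbows) vs right-angle arms (90 deg),
  # identical shoulder configuration -> elbow-channel DS = pi/2
  straight <- make_test_seq(
    n = 20,
    x_over = list(left_elbow = -1.0, right_elbow = 1.0,
                  left_wrist = -1.5, right_wrist = 1.5),
    y_over = list(left_elbow = 0, right_elbow = 0,
                  left_wrist = 0, right_wrist = 0))
  bent <- make_test_seq(
    n = 20,
    x_over = list(left_elbow = -1.0, right_elbow = 1.0,
                  left_wrist = -1.0, right_wrist = 1.0),
    y_over = list(left_elbow = 0, right_elbow = 0,
                  left_wrist = 0.5, right_wrist = 0.5))
  s <- joint_angle_similarity(straight, bent, cfg_raw, channels = "elbows")
  expect_equal(attr(s, "DS"), pi / 2, tolerance = 1e-9)

  # translation and uniform-scale invariance
  other <- cached_clip(seed = 66)
  ref <- as.numeric(joint_angle_similarity(cl$sequence, other$sequence))
  moved <- cl$sequence
  moved$x <- moved$x * 3 + 17; moved$y <- moved$y * 3 - 4
  expect_equal(as.numeric(joint_angle_similarity(moved, other$sequence)), ref,
               tolerance = 1e-9)

  collapsed <- make_test_seq(n = 20, x_over = list(left_elbow = -0.5),
                             y_over = list(left_elbow = 0))  # on the shoulder
  expect_error(joint_angle_similarity(collapsed, straight, cfg_raw),
               "degenerate")
})

test_that("trapezoid at M = 100 agrees with a fine Riemann oracle", {
  set.seed(23)
  for (i in 1:10) {
    kx <- runif(6); ky <- runif(6)
    f <- splinefun(seq(0, 1, length.out = 6), kx, method = "natural")
    g <- splinefun(seq(0, 1, length.out = 6), ky, method = "natural")
    gg <- seq(0, 1, length.out = 100)
    ds <- trajectory_area_dissimilarity(trajectory(f(gg), 0, gg[2]),
                                        trajectory(g(gg), 0, gg[2]))
    expect_equal(ds, riemann_area(f, g), tolerance = 1e-3)
  }
})
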