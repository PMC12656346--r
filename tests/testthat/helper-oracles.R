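# Independent oracles and small fixture builders shared across tests.

# Exhaustive DTW oracle: enumerate *every* monotone path (steps right, down,
# diagonal) through the local-cost matrix and return the minimum total cost.
# Exponential, usable only for tiny inputs; deliberately not the DP.
dtw_brute_force <- function(a, b) {
  a <- if (is.matrix(a)) a else matrix(a, ncol = 1)
  b <- if (is.matrix(b)) b else matrix(b, ncol = 1)
  n <- nrow(a); m <- nrow(b)
  C <- sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b))
  C <- matrix(pmax(C, 0), n, m)
  all_costs <- function(i, j) {
    if (i == n && j == m) return(C[i, j])
    out <- numeric(0)
    if (i < n) out <- c(out, all_costs(i + 1, j))
    if (j < m) out <- c(out, all_costs(i, j + 1))
    if (i < n && j < m) out <- c(out, all_costs(i + 1, j + 1))
    C[i, j] + out
  }
  min(all_costs(1, 1))
}

# Fine-grid left-Riemann oracle for the area between two sampled curves,
# independent of the trapezoid implementation under test.
riemann_area <- function(f, g, n = 100000L) {
  tt <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
  sum(abs(f(tt) - g(tt))) / n
}

# Minimal hand-built pose sequence: static skeleton with optional per-joint
# coordinate overrides (each a vector of length n or a scalar).
make_test_seq <- function(n = 30, fps = 30, units = "body_scale",
                          x_over = list(), y_over = list(),
                          clip_id = "test", player_id = "p",
                          extra_joints = character(0)) {
  joints <- unique(c("nose", "left_shoulder", "right_shoulder",
                     "left_elbow", "right_elbow", "left_wrist", "right_wrist",
                     "left_hip", "right_hip", extra_joints))
  base_x <- c(nose = 0, left_shoulder = -0.5, right_shoulder = 0.5,
              left_elbow = -0.6, right_elbow = 0.6,
              left_wrist = -0.4, right_wrist = 0.4,
              left_hip = -0.35, right_hip = 0.35)
  base_y <- c(nose = -0.6, left_shoulder = 0, right_shoulder = 0,
              left_elbow = 0.7, right_elbow = 0.7,
              left_wrist = 1.4, right_wrist = 1.4,
              left_hip = 1.5, right_hip = 1.5)
  X <- sapply(joints, function(j) rep(if (j %in% names(base_x)) base_x[[j]]
                                      else 0.1, n))
  Y <- sapply(joints, function(j) rep(if (j %in% names(base_y)) base_y[[j]]
                                      else -0.8, n))
  for (j in names(x_over)) X[, j] <- rep(x_over[[j]], length.out = n)
  for (j in names(y_over)) Y[, j] <- rep(y_over[[j]], length.out = n)
  pose_sequence(time = (seq_len(n) - 1) / fps, x = X, y = Y, fps = fps,
                units = units, clip_id = clip_id, player_id = player_id)
}

# Pose sequence carrying the full 33-landmark set in pixel units, for the
# landmark-record dialect tests.
make_landmark_seq <- function(n = 12, fps = 30) {
  t <- (seq_len(n) - 1) / fps
  X <- sapply(blazepose_landmarks, function(j)
    480 + 40 * sin(2 * pi * t + match(j, blazepose_landmarks)))
  Y <- sapply(blazepose_landmarks, function(j)
    270 + 30 * cos(2 * pi * t + match(j, blazepose_landmarks)))
  pose_sequence(time = t, x = X, y = Y, fps = fps, units = "pixels",
                clip_id = "lm", player_id = "p1")
}

# A default-style synthetic clip, cached per (seed, sigma) to keep the test
# suite fast.
cached_clip <- local({
  cache <- list()
  function(seed = 1, noise_sigma = 0.01, ...) {
    key <- paste(seed, noise_sigma, ...)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_swing(swing_style(noise_sigma = noise_sigma,
                                                  seed = seed, ...))
    cache[[key]]
  }
})
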