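#' Similarity configuration
#'
#' @param joints joint labels entering the comparison; default wrists,
#'   elbows, shoulders and hips (8 joints).
#' @param weights per-joint non-negative weights: `NULL` for uniform, the
#'   string `"biomech"` for a preset emphasizing the hands and hip/trunk
#'   channel (wrists 2.0, hips 1.5, elbows 1.0, shoulders 1.0), or a named
#'   numeric vector covering `joints`.
#' @param samples_per_phase number `M` of uniform samples each phase is
#'   resampled to before integration (default 100).
#' @param lambda positive scale of the dissimilarity-to-similarity map:
#'   a dissimilarity equal to `lambda` maps to similarity 0.5.
#' @param method one of `"dmsm"`, `"dtw_cosine"`, `"euclidean"`,
#'   `"pearson"`, `"joint_angle"`.
#' @param time_normalize rescale each phase's time axis to \[0, 1\] before
#'   integration (default `TRUE`), so the integral measures path difference
#'   rather than tempo difference; with `FALSE` the unit-interval integral is
#'   scaled back by the mean of the two phase durations (unit-seconds).
#' @param preprocess a [preprocess_config()] used when raw clips are passed
#'   to the comparison functions.
#' @return A `similarity_config` list.
#' @export
similarity_config <- function(joints = c("left_wrist", "right_wrist",
                                         "left_elbow", "right_elbow",
                                         "left_shoulder", "right_shoulder",
                                         "left_hip", "right_hip"),
                              weights = NULL,
                              samples_per_phase = 100L,
                              lambda = 1.0,
                              method = c("dmsm", "dtw_cosine", "euclidean",
                                         "pearson", "joint_angle"),
                              time_normalize = TRUE,
                              preprocess = preprocess_config()) {
  method <- match.arg(method)
  samples_per_phase <- as.integer(samples_per_phase)
  if (samples_per_phase < 2L) stop("samples_per_phase must be >= 2",
                                   call. = FALSE)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  if (identical(weights, "biomech")) {
    weights <- stats::setNames(rep(1, length(joints)), joints)
    weights[grepl("wrist", joints)] <- 2.0
    weights[grepl("hip", joints)] <- 1.5
  }
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(joints)), joints)
  } else {
    if (is.null(names(weights)) || !all(joints %in% names(weights)))
      stop("weights must be named and cover every included joint",
           call. = FALSE)
    weights <- weights[joints]
  }
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum", call. = FALSE)
  structure(list(joints = joints, weights = weights,
                 samples_per_phase = samples_per_phase, lambda = lambda,
                 method = method, time_normalize = time_normalize,
                 preprocess = preprocess),
            class = "similarity_config")
}

#' Area dissimilarity between two trajectories
#'
#' The trapezoidal approximation of the integral of the absolute difference
#' between two 1D trajectories sampled on the *same* uniform grid:
#' `DS = integral |x(t) - y(t)| dt`. This is the L1 distance between the
#' sampled curves (weighted by the grid spacing), so it is non-negative,
#' symmetric, zero exactly when the samples coincide, and satisfies the
#' triangle inequality. Computed in a single O(N) pass.
#'
#' @param x,y [trajectory()] objects on identical grids (same length, same
#'   `dt`; the caller resamples first if necessary).
#' @return Non-negative numeric dissimilarity.
#' @export
trajectory_area_dissimilarity <- function(x, y) {
  stopifnot(inherits(x, "trajectory"), inherits(y, "trajectory"))
  n <- length(x$values)
  if (n != length(y$values) || abs(x$dt - y$dt) > 1e-9 * max(x$dt, y$dt))
    stop("trajectories must share one uniform grid; resample first",
         call. = FALSE)
  d <- abs(x$values - y$values)
  x$dt * (sum(d) - (d[1] + d[n]) / 2)
}

#' Map a dissimilarity onto the (0, 1] similarity scale
#'
#' `similarity = 1 / (1 + DS / lambda)`: strictly decreasing in `DS`, equal
#' to 1 at `DS = 0`, equal to 0.5 at `DS = lambda`, and approaching 0 as
#' `DS` grows.
#'
#' @param DS non-negative dissimilarity.
#' @param lambda positive scale.
#' @return Similarity in (0, 1].
#' @export
dissimilarity_to_similarity <- function(DS, lambda = 1.0) {
  if (any(DS < 0)) stop("dissimilarity must be non-negative", call. = FALSE)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  1 / (1 + DS / lambda)
}

# One joint coordinate of a phase slice as a time-normalized trajectory with
# M samples on [0, 1]. Single-frame slices become constant trajectories.
slice_traj <- function(slice, joint, coord, M, interp = "cubic") {
  v <- if (coord == "x") slice$x[, joint] else slice$y[, joint]
  if (length(v) < 2L)
    return(trajectory(rep(v, M), t0 = 0, dt = 1 / (M - 1)))
  time_normalize(slice$time, v, M = M, method = interp)
}

slice_duration <- function(slice) {
  if (length(slice$time) < 2L) return(0)
  slice$time[length(slice$time)] - slice$time[1]
}

#' Phase-wise dissimilarity between two swing slices
#'
#' For every included joint, the x- and y-trajectories of the two slices are
#' rescaled to the unit time interval, resampled to `M` samples, and their
#' area dissimilarities averaged; the per-joint values are then combined with
#' the configured weights, and mapped to a similarity.
#'
#' @param sliceA,sliceB same-phase [pose_sequence()] slices, body-scale
#'   normalized and address-aligned.
#' @param cfg a [similarity_config()].
#' @return A `phase_score` list with `phase_name`, `per_joint_DS`,
#'   `weighted_DS` and `similarity`.
#' @export
phase_dissimilarity <- function(sliceA, sliceB, cfg = similarity_config()) {
  if (length(sliceA$time) < 1L || length(sliceB$time) < 1L)
    stop("validation error: empty phase slice", call. = FALSE)
  missing <- setdiff(cfg$joints, intersect(joint_names(sliceA),
                                           joint_names(sliceB)))
  if (length(missing))
    stop("validation error: joint(s) absent from both clips' shared set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  M <- cfg$samples_per_phase
  interp <- cfg$preprocess$interp
  ds <- vapply(cfg$joints, function(j) {
    dsx <- trajectory_area_dissimilarity(
      slice_traj(sliceA, j, "x", M, interp),
      slice_traj(sliceB, j, "x", M, interp))
    dsy <- trajectory_area_dissimilarity(
      slice_traj(sliceA, j, "y", M, interp),
      slice_traj(sliceB, j, "y", M, interp))
    (dsx + dsy) / 2
  }, numeric(1))
  if (!cfg$time_normalize)
    ds <- ds * (slice_duration(sliceA) + slice_duration(sliceB)) / 2
  w <- cfg$weights
  weighted <- sum(w * ds) / sum(w)
  structure(list(phase_name = attr(sliceA, "phase") %||% NA_character_,
                 per_joint_DS = ds,
                 weighted_DS = weighted,
                 similarity = dissimilarity_to_similarity(weighted,
                                                          cfg$lambda)),
            class = "phase_score")
}

# Accept either a raw pose_sequence or an already-prepared swing.
as_prepared <- function(x, cfg) {
  if (inherits(x, "prepared_swing")) return(x)
  prepare_swing(x, cfg$preprocess)
}

#' Dynamic motion similarity between two swings
#'
#' The full phase-aware comparison: each clip is (if not already prepared)
#' body-scale normalized, smoothed, cropped to the swing window when longer
#' than it, segmented into the seven phases from its *own* kinematic cues (no
#' cross-clip frame alignment), and centered on its address-phase mid-hip.
#' Corresponding phases are then compared with [phase_dissimilarity()].
#'
#' @param seqA,seqB [pose_sequence()] clips or `prepared_swing` objects from
#'   [prepare_swing()]/[as_prepared()].
#' @param cfg a [similarity_config()].
#' @return A `similarity_report` with 7 phase scores, the weight-free mean of
#'   the phase similarities (`overall_similarity`) and the mean weighted
#'   phase dissimilarity (`overall_DS`).
#' @export
dmsm_compare <- function(seqA, seqB, cfg = similarity_config()) {
  seq_of <- function(x) if (inherits(x, "prepared_swing")) x$seq else x
  idA <- seq_of(seqA)$clip_id
  idB <- seq_of(seqB)$clip_id
  shared <- intersect(joint_names(seq_of(seqA)), joint_names(seq_of(seqB)))
  missing <- setdiff(cfg$joints, shared)
  if (length(missing))
    stop("validation error: clip joint sets lack: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pA <- tryCatch(as_prepared(seqA, cfg), error = function(e)
    stop("clip '", idA, "': ", conditionMessage(e), call. = FALSE))
  pB <- tryCatch(as_prepared(seqB, cfg), error = function(e)
    stop("clip '", idB, "': ", conditionMessage(e), call. = FALSE))
  slA <- phase_slices(pA$seq, pA$seg)
  slB <- phase_slices(pB$seq, pB$seg)
  scores <- lapply(seq_along(phase_names), function(k)
    phase_dissimilarity(slA[[k]], slB[[k]], cfg))
  names(scores) <- phase_names
  sims <- vapply(scores, `[[`, numeric(1), "similarity")
  dss <- vapply(scores, `[[`, numeric(1), "weighted_DS")
  structure(list(clip_ids = c(idA, idB), method = "dmsm",
                 phase_scores = scores,
                 overall_similarity = mean(sims),
                 overall_DS = mean(dss)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report> %s vs %s (method: %s)\n",
              x$clip_ids[1], x$clip_ids[2], x$method))
  for (s in x$phase_scores)
    cat(sprintf("  %-8s weighted DS %.4f  similarity %.4f\n",
                s$phase_name, s$weighted_DS, s$similarity))
  cat(sprintf("  overall similarity %.4f | overall DS %.4f\n",
              x$overall_similarity, x$overall_DS))
  invisible(x)
}

#' @export
as.data.frame.similarity_report <- function(x, ...) {
  do.call(rbind, lapply(x$phase_scores, function(s)
    data.frame(phase = s$phase_name, weighted_DS = s$weighted_DS,
               similarity = s$similarity, row.names = NULL)))
}

#' Dynamic time warping alignment
#'
#' Standard dynamic-programming DTW with steps (1,0), (0,1), (1,1) and
#' Euclidean local cost, returning the optimal monotone warping path and its
#' total cost. Ties during backtracking prefer the diagonal step, then the
#' step in `a`, for determinism.
#'
#' @param a,b numeric matrices (rows = time steps, columns = feature
#'   dimensions) or plain vectors.
#' @return A list with `path` (2-column matrix of 1-based index pairs) and
#'   `cost`.
#' @export
dtw_align <- function(a, b) {
  a <- if (is.matrix(a)) a else matrix(a, ncol = 1)
  b <- if (is.matrix(b)) b else matrix(b, ncol = 1)
  n <- nrow(a); m <- nrow(b)
  if (n == 0L || m == 0L)
    stop("validation error: empty sequence in DTW", call. = FALSE)
  # local Euclidean cost matrix in one shot
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  C <- sqrt(pmax(sq, 0))
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- C[i, j] +
        min(D[i, j], D[i, j + 1L], D[i + 1L, j])
    }
  }
  # backtrack
  path <- matrix(NA_integer_, n + m, 2L)
  k <- 0L
  i <- n; j <- m
  repeat {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i == 1L && j == 1L) break
    if (i > 1L && j > 1L && D[i, j] <= D[i, j + 1L] && D[i, j] <= D[i + 1L, j]) {
      i <- i - 1L; j <- j - 1L
    } else if (i > 1L && (j == 1L || D[i, j + 1L] <= D[i + 1L, j])) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(path = path[k:1, , drop = FALSE], cost = D[n + 1L, m + 1L])
}

# normalize + smooth + conditional crop, *without* address centering or
# segmentation: the preparation the frame-based baselines operate on.
prep_basic <- function(x, cfg) {
  if (inherits(x, "prepared_swing")) return(x$basic)
  seq <- x
  validate_pose_sequence(seq)
  if (seq$units == "pixels") seq <- normalize_body_scale(seq)
  seq <- smooth_pose_sequence(seq, cfg$preprocess$smoothing_window)
  dur <- seq$time[length(seq$time)] - seq$time[1]
  if (dur > cfg$preprocess$crop_before_s + cfg$preprocess$crop_after_s)
    seq <- crop_pipeline(seq, cfg$preprocess)
  seq
}

motion_vectors <- function(seq, joints) {
  dx <- apply(seq$x[, joints, drop = FALSE], 2, diff)
  dy <- apply(seq$y[, joints, drop = FALSE], 2, diff)
  cbind(dx, dy)
}

#' DTW + cosine baseline similarity
#'
#' The conventional frame-alignment baseline: per-frame motion vectors (the
#' concatenated per-joint coordinate deltas between successive frames) are
#' DTW-aligned between the two clips, and the result is the mean cosine
#' similarity over aligned vector pairs. Pairs where either vector norm is
#' below 1e-9 (no motion) are skipped rather than treated as defined.
#'
#' @param seqA,seqB clips or prepared swings.
#' @param cfg a [similarity_config()].
#' @return Mean cosine similarity in \[-1, 1\].
#' @export
dtw_cosine_similarity <- function(seqA, seqB, cfg = similarity_config()) {
  A <- motion_vectors(prep_basic(seqA, cfg), cfg$joints)
  B <- motion_vectors(prep_basic(seqB, cfg), cfg$joints)
  nA <- sqrt(rowSums(A^2)); nB <- sqrt(rowSums(B^2))
  if (all(nA < 1e-9) || all(nB < 1e-9))
    stop("undefined similarity: clip is static (all motion vectors ~ 0)",
         call. = FALSE)
  al <- dtw_align(A, B)
  i <- al$path[, 1]; j <- al$path[, 2]
  keep <- nA[i] >= 1e-9 & nB[j] >= 1e-9
  if (!any(keep))
    stop("undefined similarity: no aligned pair with non-zero motion",
         call. = FALSE)
  cosims <- rowSums(A[i[keep], , drop = FALSE] * B[j[keep], , drop = FALSE]) /
    (nA[i[keep]] * nB[j[keep]])
  mean(cosims)
}

#' Euclidean baseline similarity
#'
#' Direct pose-vector comparison without temporal alignment: both clips are
#' resampled to the shorter clip's frame count, and the dissimilarity is the
#' mean over frames of the root-mean-square per-joint coordinate distance (so
#' a uniform offset of `d` body-scale units on every joint gives `DS = d`).
#' No address alignment is applied — translation sensitivity is a documented
#' weakness of this baseline.
#'
#' @param seqA,seqB clips or prepared swings.
#' @param cfg a [similarity_config()].
#' @return Similarity in (0, 1]; the underlying `DS` is in the `"DS"`
#'   attribute.
#' @export
euclidean_similarity <- function(seqA, seqB, cfg = similarity_config()) {
  A <- prep_basic(seqA, cfg)
  B <- prep_basic(seqB, cfg)
  n <- min(length(A$time), length(B$time))
  rs <- function(s) {
    sapply(cfg$joints, function(j) c(
      resample_uniform(trajectory(s$x[, j], s$time[1],
                                  mean(diff(s$time))), n,
                       cfg$preprocess$interp)$values,
      resample_uniform(trajectory(s$y[, j], s$time[1],
                                  mean(diff(s$time))), n,
                       cfg$preprocess$interp)$values))
  }
  MA <- rs(A); MB <- rs(B)  # 2n rows (x then y stacked), J cols
  d2 <- (MA - MB)^2
  per_frame <- sqrt((rowSums(d2[1:n, , drop = FALSE]) +
                       rowSums(d2[(n + 1):(2 * n), , drop = FALSE])) /
                      length(cfg$joints))
  DS <- mean(per_frame)
  structure(dissimilarity_to_similarity(DS, cfg$lambda), DS = DS)
}

#' Phase-wise Pearson correlation baseline
#'
#' Mean Pearson correlation between the time-normalized, resampled x/y
#' trajectories of the included joints over one phase. Channels that are
#' constant in either slice have no defined correlation and are excluded
#' with a warning; if every channel is excluded the result is an error.
#'
#' @param sliceA,sliceB same-phase slices.
#' @param cfg a [similarity_config()].
#' @return Mean correlation in \[-1, 1\].
#' @export
pearson_phase_correlation <- function(sliceA, sliceB,
                                      cfg = similarity_config()) {
  M <- cfg$samples_per_phase
  interp <- cfg$preprocess$interp
  vals <- c()
  dropped <- character(0)
  for (j in cfg$joints) for (coord in c("x", "y")) {
    a <- slice_traj(sliceA, j, coord, M, interp)$values
    b <- slice_traj(sliceB, j, coord, M, interp)$values
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
      dropped <- c(dropped, paste0(j, "_", coord))
    } else {
      vals <- c(vals, stats::cor(a, b))
    }
  }
  if (length(dropped) && length(vals))
    warning("constant trajectory channel(s) excluded from correlation: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (!length(vals))
    stop("undefined correlation: every trajectory channel is constant",
         call. = FALSE)
  mean(vals)
}

# Interior angle (radians) at vertex B of the polyline A-B-C, per frame.
interior_angle <- function(seq, a, b, c) {
  ux <- seq$x[, a] - seq$x[, b]; uy <- seq$y[, a] - seq$y[, b]
  vx <- seq$x[, c] - seq$x[, b]; vy <- seq$y[, c] - seq$y[, b]
  nu <- sqrt(ux^2 + uy^2); nv <- sqrt(vx^2 + vy^2)
  if (any(nu < 1e-12) || any(nv < 1e-12))
    stop("degenerate skeleton: zero-length limb segment at joint '", b, "'",
         call. = FALSE)
  acos(pmin(pmax((ux * vx + uy * vy) / (nu * nv), -1), 1))
}

#' Joint-angle baseline similarity
#'
#' A local-biomechanics metric in the spirit of pose-similarity measures
#' built on joint angles: per frame, the interior angles at both elbows
#' (shoulder-elbow-wrist) and both shoulders (hip-shoulder-elbow) are
#' computed; the four angle trajectories are time-normalized and resampled to
#' a common grid, and the dissimilarity is the mean absolute angle difference
#' in radians, mapped to a similarity with scale `lambda = pi/6` (a 30-degree
#' mean difference scores 0.5). Angles are invariant to global translation
#' and uniform scaling of either clip.
#'
#' @param seqA,seqB clips or prepared swings (elbows, shoulders, hips and
#'   wrists required).
#' @param cfg a [similarity_config()].
#' @param channels which angle channels enter the mean: `"elbows"`,
#'   `"shoulders"`, or both (default).
#' @return Similarity in (0, 1]; the underlying `DS` (radians) is in the
#'   `"DS"` attribute.
#' @export
joint_angle_similarity <- function(seqA, seqB, cfg = similarity_config(),
                                   channels = c("elbows", "shoulders")) {
  channels <- match.arg(channels, several.ok = TRUE)
  A <- prep_basic(seqA, cfg)
  B <- prep_basic(seqB, cfg)
  need <- c("left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
            "left_wrist", "right_wrist", "left_hip", "right_hip")
  if (!has_joints(A, need) || !has_joints(B, need))
    stop("joint-angle baseline requires elbows, shoulders, hips and wrists",
         call. = FALSE)
  channels <- c(
    if ("elbows" %in% channels) list(
      c("left_shoulder", "left_elbow", "left_wrist"),
      c("right_shoulder", "right_elbow", "right_wrist")),
    if ("shoulders" %in% channels) list(
      c("left_hip", "left_shoulder", "left_elbow"),
      c("right_hip", "right_shoulder", "right_elbow")))
  M <- cfg$samples_per_phase
  diffs <- vapply(channels, function(ch) {
    ta <- time_normalize(A$time, interior_angle(A, ch[1], ch[2], ch[3]),
                         M, cfg$preprocess$interp)
    tb <- time_normalize(B$time, interior_angle(B, ch[1], ch[2], ch[3]),
                         M, cfg$preprocess$interp)
    mean(abs(ta$values - tb$values))
  }, numeric(1))
  DS <- mean(diffs)
  structure(dissimilarity_to_similarity(DS, pi / 6), DS = DS)
}

#' Compare two swings with any configured method
#'
#' Dispatcher used by the evaluation harness: every method returns both a
#' similarity and a dissimilarity on a common footing (`DS = 1 - similarity`
#' for the correlation-type methods that have no natural integral scale).
#'
#' @param seqA,seqB clips or prepared swings.
#' @param method method id (defaults to `cfg$method`).
#' @param cfg a [similarity_config()].
#' @return A list with `similarity`, `DS`, and for DMSM the full `report`.
#' @export
compare_swings <- function(seqA, seqB, method = NULL,
                           cfg = similarity_config()) {
  method <- method %||% cfg$method
  switch(
    method,
    dmsm = {
      rep <- dmsm_compare(seqA, seqB, cfg)
      list(similarity = rep$overall_similarity, DS = rep$overall_DS,
           report = rep)
    },
    dtw_cosine = {
      s <- dtw_cosine_similarity(seqA, seqB, cfg)
      list(similarity = s, DS = 1 - s)
    },
    euclidean = {
      s <- euclidean_similarity(seqA, seqB, cfg)
      list(similarity = as.numeric(s), DS = attr(s, "DS"))
    },
    pearson = {
      pA <- as_prepared(seqA, cfg); pB <- as_prepared(seqB, cfg)
      slA <- phase_slices(pA$seq, pA$seg)
      slB <- phase_slices(pB$seq, pB$seg)
      rs <- suppressWarnings(vapply(1:7, function(k)
        tryCatch(pearson_phase_correlation(slA[[k]], slB[[k]], cfg),
                 error = function(e) NA_real_), numeric(1)))
      if (all(is.na(rs)))
        stop("undefined correlation in every phase", call. = FALSE)
      s <- mean(rs, na.rm = TRUE)
      list(similarity = s, DS = 1 - s)
    },
    joint_angle = {
      s <- joint_angle_similarity(seqA, seqB, cfg)
      list(similarity = as.numeric(s), DS = attr(s, "DS"))
    },
    stop("unknown method: ", method, call. = FALSE)
  )
}
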