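#' Spine-angle trajectory
#'
#' Per-frame angle, in degrees, between the mid-hip to mid-shoulder segment
#' (the standard 2D surrogate for the spine; no spine landmark exists in the
#' 33-point set) and the image vertical: 0 = upright, 90 = horizontal trunk,
#' values in \[0, 180). Invariant to translation and uniform scaling of the
#' coordinates.
#'
#' @param seq a [pose_sequence()] (or `prepared_swing`) with shoulders and
#'   hips.
#' @return A [trajectory()] in degrees on the clip's frame grid.
#' @export
spine_angle_trajectory <- function(seq) {
  if (inherits(seq, "prepared_swing")) seq <- seq$seq
  vx <- midpoint_x(seq, "left_shoulder", "right_shoulder") -
    midpoint_x(seq, "left_hip", "right_hip")
  vy <- midpoint_y(seq, "left_shoulder", "right_shoulder") -
    midpoint_y(seq, "left_hip", "right_hip")
  nv <- sqrt(vx^2 + vy^2)
  if (any(nv < 1e-12))
    stop("degenerate skeleton: mid-hip and mid-shoulder coincide",
         call. = FALSE)
  ang <- acos(pmin(pmax(-vy / nv, -1), 1)) * 180 / pi
  trajectory(ang, t0 = seq$time[1], dt = mean(diff(seq$time)))
}

#' Spine-angle trajectory difference between two swings
#'
#' The area dissimilarity (degrees, time-normalized) between the two
#' spine-angle trajectories over the backswing-through-impact region (phases
#' takeaway..impact by default): the region where trunk stability
#' distinguishes swing quality; the long static finish pose would otherwise
#' dominate the integral. Symmetric in its arguments and zero for identical
#' angle trajectories.
#'
#' @param seqA,seqB clips or `prepared_swing` objects (segmentation is run if
#'   needed).
#' @param phases character vector `c(first, last)` naming the phase range to
#'   integrate over; default `c("takeaway", "impact")`.
#' @param M number of time-normalized samples (default 100).
#' @param cfg a [similarity_config()] supplying the preprocessing settings.
#' @return Non-negative difference in degrees.
#' @export
spine_angle_delta <- function(seqA, seqB, phases = c("takeaway", "impact"),
                              M = 100L, cfg = similarity_config()) {
  pA <- as_prepared(seqA, cfg)
  pB <- as_prepared(seqB, cfg)
  ks <- match(phases, phase_names)
  if (anyNA(ks) || ks[1] > ks[2])
    stop("invalid phase range: ", paste(phases, collapse = ".."),
         call. = FALSE)
  region <- function(p) {
    b <- p$seg$boundaries
    idx <- seq.int(b[ks[1]], b[ks[2] + 1L] - 1L)
    ang <- spine_angle_trajectory(p$seq)
    time_normalize(p$seq$time[idx], ang$values[idx], M = M,
                   method = cfg$preprocess$interp)
  }
  trajectory_area_dissimilarity(region(pA), region(pB))
}

#' Matched backswing/downswing frame analysis
#'
#' Finds the backswing frame (takeaway..top) and the downswing frame (the
#' top-to-impact phase) at which the joint's height is closest to a reference
#' height, and compares the joint's *x* position at those two height-matched
#' frames. At the default shoulder-height reference the wrist path is near
#' its horizontal extremum, so the x comparison is robust to frame
#' quantization and reads out the backswing-vs-downswing plane separation
#' directly: a downswing path inside the backswing path (negative x gap,
#' pro-like) is labeled `downswing_lower`, the converse (amateur-like)
#' `backswing_lower`, and gaps under `tol` are `indeterminate`.
#'
#' @param seq a clip or `prepared_swing` (segmentation run if needed).
#' @param joint joint to track; default the lead wrist for the clip's
#'   handedness. Left-handed clips are folded to the right-handed frame
#'   before analysis, so labels are handedness-independent.
#' @param reference `"shoulder_height"` (clip-mean lead-shoulder y) or a
#'   numeric y value in body-scale units.
#' @param tol x-gap (body-scale units) below which the result is
#'   `indeterminate`; default 0.01, below pose-estimator jitter.
#' @param approach_tol maximum allowed |y - reference| (body-scale units) of
#'   the best-matching frame in each region; beyond it the reference is never
#'   approached and an error is raised. Default 0.1.
#' @param cfg a [similarity_config()].
#' @return A `matched_frame_pair` list: `reference_height`,
#'   `backswing_frame`, `top_frame`, `downswing_frame`, `backswing_x`,
#'   `downswing_x`, `backswing_y`, `downswing_y`, and `label` in
#'   `{backswing_lower, downswing_lower, indeterminate}`.
#' @export
matched_frame_analysis <- function(seq, joint = NULL,
                                   reference = "shoulder_height",
                                   tol = 0.01, approach_tol = 0.1,
                                   cfg = similarity_config()) {
  p <- as_prepared(seq, cfg)
  s <- p$raw  # unsmoothed: the moving average flattens the path extrema
  if (s$handedness == "left") s <- mirror_pose_sequence(s)
  joint <- joint %||% "left_wrist"  # lead wrist after folding to right-handed
  if (!has_joints(s, joint))
    stop("joint '", joint, "' not present in clip", call. = FALSE)
  ref <- if (identical(reference, "shoulder_height"))
    mean(s$y[, "left_shoulder"]) else as.numeric(reference)
  b <- p$seg$boundaries
  back_idx <- seq.int(b[2], b[4] - 1L)   # takeaway + half
  # downswing = top..impact only: the follow-through re-crosses the reference
  # height on the target side of the body and must not win the match
  down_idx <- seq.int(b[5], b[6] - 1L)
  # sub-frame matching: cubic-upsample each region 8x so the height match is
  # not biased by frame quantization at downswing speeds
  pick <- function(idx, what) {
    tt <- s$time[idx]
    td <- seq(tt[1], tt[length(tt)], length.out = 8L * length(idx))
    yd <- interp_values(tt, s$y[idx, joint], td, cfg$preprocess$interp)
    k <- which.min(abs(yd - ref))
    if (abs(yd[k] - ref) > approach_tol)
      stop("no match: reference height never approached within ",
           approach_tol, " units in the ", what, " region", call. = FALSE)
    list(frame = idx[which.min(abs(tt - td[k]))],
         x = interp_values(tt, s$x[idx, joint], td[k], cfg$preprocess$interp),
         y = yd[k])
  }
  bs <- pick(back_idx, "backswing")
  ds <- pick(down_idx, "downswing")
  gap <- ds$x - bs$x
  label <- if (abs(gap) < tol) "indeterminate"
  else if (gap < 0) "downswing_lower" else "backswing_lower"
  structure(list(reference_height = ref,
                 backswing_frame = bs$frame, top_frame = b[4],
                 downswing_frame = ds$frame,
                 backswing_x = bs$x, downswing_x = ds$x,
                 backswing_y = bs$y, downswing_y = ds$y,
                 label = label),
            class = "matched_frame_pair")
}

#' @export
print.matched_frame_pair <- function(x, ...) {
  cat(sprintf(
    "<matched_frame_pair> ref y = %.3f | backswing f%d (x %.3f) vs downswing f%d (x %.3f) -> %s\n",
    x$reference_height, x$backswing_frame, x$backswing_x,
    x$downswing_frame, x$downswing_x, x$label))
  invisible(x)
}
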