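#' Pose-keypoint sequence for one swing clip
#'
#' A `pose_sequence` stores a time-ordered set of 2D joint coordinates for a
#' single clip, in image coordinates: origin top-left, y increasing
#' *downward*, so "higher" on the body means smaller y. Coordinates are either
#' raw pixels (`units = "pixels"`) or body-scale units after
#' [normalize_body_scale()] (`units = "body_scale"`, shoulder width = 1).
#'
#' @param time numeric vector of frame times in seconds, strictly increasing.
#' @param x,y numeric matrices, one row per frame, one named column per joint.
#' @param fps nominal frame rate (frames/second); must agree with the median
#'   inter-frame interval within 5%.
#' @param units `"pixels"` or `"body_scale"`.
#' @param handedness `"right"` or `"left"`; the lead wrist (nearer the
#'   target) is the left wrist for a right-handed player.
#' @param clip_id,player_id opaque identifier strings.
#' @param conf optional confidence matrix (same shape as `x`), values in
#'   \[0, 1\].
#'
#' @return An object of class `pose_sequence`.
#' @seealso [read_pose_sequence()], [generate_swing()]
#' @export
pose_sequence <- function(time, x, y, fps,
                          units = c("pixels", "body_scale"),
                          handedness = c("right", "left"),
                          clip_id = "clip", player_id = "player",
                          conf = NULL) {
  units <- match.arg(units)
  handedness <- match.arg(handedness)
  x <- as.matrix(x)
  y <- as.matrix(y)
  seq <- structure(
    list(time = as.numeric(time), x = x, y = y, conf = conf,
         fps = as.numeric(fps), units = units, handedness = handedness,
         clip_id = as.character(clip_id), player_id = as.character(player_id)),
    class = "pose_sequence"
  )
  validate_pose_sequence(seq)
}

#' Validate a pose sequence
#'
#' Enforces the container invariants: at least two frames, strictly
#' increasing times, finite coordinates, identical joint sets across frames
#' (guaranteed by the matrix layout), presence of the minimal joint set, and
#' fps consistent with the median inter-frame interval within 5%.
#'
#' @param seq a [pose_sequence()].
#' @return `seq`, invisibly unchanged, or an error.
#' @export
validate_pose_sequence <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  n <- length(seq$time)
  if (n < 2L)
    stop("pose_sequence must have at least 2 frames, got ", n, call. = FALSE)
  if (any(diff(seq$time) <= 0))
    stop("pose_sequence frame times must be strictly increasing", call. = FALSE)
  if (!is.matrix(seq$x) || !is.matrix(seq$y) ||
      nrow(seq$x) != n || nrow(seq$y) != n)
    stop("coordinate matrices must have one row per frame", call. = FALSE)
  if (is.null(colnames(seq$x)) || !identical(colnames(seq$x), colnames(seq$y)))
    stop("x and y must carry identical joint column names", call. = FALSE)
  if (!all(is.finite(seq$x)) || !all(is.finite(seq$y)))
    stop("all coordinate values must be finite", call. = FALSE)
  missing <- setdiff(required_joints, colnames(seq$x))
  if (length(missing))
    stop("missing required joint(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(seq$fps) || length(seq$fps) != 1L || seq$fps <= 0)
    stop("fps must be a single positive number", call. = FALSE)
  med_dt <- stats::median(diff(seq$time))
  if (abs(1 / med_dt - seq$fps) > 0.05 * seq$fps)
    stop(sprintf(
      "fps (%.3f) inconsistent with median inter-frame interval (%.4f s)",
      seq$fps, med_dt), call. = FALSE)
  if (!is.null(seq$conf)) {
    if (!is.matrix(seq$conf) || !identical(dim(seq$conf), dim(seq$x)))
      stop("conf must match the coordinate matrices in shape", call. = FALSE)
    if (any(seq$conf < 0 | seq$conf > 1, na.rm = TRUE))
      stop("confidence values must lie in [0, 1]", call. = FALSE)
  }
  invisible(seq)
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf(
    "<pose_sequence> clip '%s' (player '%s'): %d frames @ %g fps, %.2f s\n",
    x$clip_id, x$player_id, length(x$time), x$fps,
    x$time[length(x$time)] - x$time[1]))
  cat(sprintf("  units: %s | handedness: %s | joints: %d (%s%s)\n",
              x$units, x$handedness, ncol(x$x),
              paste(utils::head(colnames(x$x), 4), collapse = ", "),
              if (ncol(x$x) > 4) ", ..." else ""))
  invisible(x)
}

#' @export
length.pose_sequence <- function(x) length(x$time)

joint_names <- function(seq) colnames(seq$x)

has_joints <- function(seq, joints) all(joints %in% colnames(seq$x))

#' Extract a contiguous frame range as a new pose sequence
#'
#' @param seq a [pose_sequence()].
#' @param idx integer vector of contiguous frame indices (1-based).
#' @return A `pose_sequence` over the selected frames.
#' @keywords internal
#' @export
subset_frames <- function(seq, idx) {
  idx <- as.integer(idx)
  if (!length(idx) || any(idx < 1L | idx > length(seq$time)))
    stop("frame index out of range", call. = FALSE)
  out <- seq
  out$time <- seq$time[idx]
  out$x <- seq$x[idx, , drop = FALSE]
  out$y <- seq$y[idx, , drop = FALSE]
  if (!is.null(seq$conf)) out$conf <- seq$conf[idx, , drop = FALSE]
  out
}

#' Mirror a pose sequence horizontally
#'
#' Reflects all x coordinates about a vertical axis (by default the clip-mean
#' mid-shoulder x) and, because a mirrored right-handed golfer is a
#' left-handed golfer, swaps the left/right joint labels and toggles the
#' handedness flag. Used to fold left-handed swings onto the right-handed
#' detection path and by the synthetic generator to produce left-handed
#' clips. Mirroring twice about the same axis restores the input exactly.
#'
#' @param seq a [pose_sequence()].
#' @param axis_x reflection axis; default the mean mid-shoulder x.
#' @param swap_sides swap `left_*`/`right_*` joint labels and the handedness
#'   flag (default `TRUE`).
#' @return The mirrored `pose_sequence`.
#' @export
mirror_pose_sequence <- function(seq, axis_x = NULL, swap_sides = TRUE) {
  if (is.null(axis_x))
    axis_x <- mean((seq$x[, "left_shoulder"] + seq$x[, "right_shoulder"]) / 2)
  out <- seq
  out$x <- 2 * axis_x - seq$x
  colnames(out$x) <- colnames(seq$x)
  if (swap_sides) {
    swapped <- swap_side_labels(colnames(seq$x))
    colnames(out$x) <- swapped
    colnames(out$y) <- swapped
    out$x <- out$x[, colnames(seq$x), drop = FALSE]
    out$y <- out$y[, colnames(seq$y), drop = FALSE]
    if (!is.null(out$conf)) {
      colnames(out$conf) <- swapped
      out$conf <- out$conf[, colnames(seq$x), drop = FALSE]
    }
    out$handedness <- if (seq$handedness == "right") "left" else "right"
  }
  out
}

swap_side_labels <- function(nm) {
  out <- nm
  out[startsWith(nm, "left_")] <- sub("^left_", "right_",
                                      nm[startsWith(nm, "left_")])
  out[startsWith(nm, "right_")] <- sub("^right_", "left_",
                                       nm[startsWith(nm, "right_")])
  out
}

# Mid-point helpers (row-wise across frames).
midpoint_x <- function(seq, a, b) (seq$x[, a] + seq$x[, b]) / 2
midpoint_y <- function(seq, a, b) (seq$y[, a] + seq$y[, b]) / 2
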