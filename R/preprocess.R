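#' Preprocessing configuration
#'
#' @param smoothing_window odd moving-average window in frames (default 5).
#' @param resample_hz target uniform resampling rate for trajectory work
#'   (default 120 Hz, 4x a 30 fps source; must not be below the input fps).
#' @param body_scale_reference currently `"shoulder_width"` only.
#' @param crop_before_s,crop_after_s swing-window extent around the detected
#'   onset (defaults 2 s before, 1 s after).
#' @param interp interpolation kind, `"cubic"` (monotone-preserving, default)
#'   or `"linear"`.
#' @param onset_threshold swing-onset speed threshold in body-scale units per
#'   frame at 30 fps; internally rescaled by `30 / fps` for other rates.
#'   Roughly 2% of shoulder width per frame separates setup sway from the
#'   takeaway.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(smoothing_window = 5L,
                              resample_hz = 120,
                              body_scale_reference = "shoulder_width",
                              crop_before_s = 2.0,
                              crop_after_s = 1.0,
                              interp = c("cubic", "linear"),
                              onset_threshold = 0.02) {
  interp <- match.arg(interp)
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L)
    stop("smoothing_window must be odd and >= 1", call. = FALSE)
  body_scale_reference <- match.arg(body_scale_reference, "shoulder_width")
  stopifnot(resample_hz > 0, crop_before_s >= 0, crop_after_s >= 0,
            onset_threshold > 0)
  structure(list(smoothing_window = smoothing_window,
                 resample_hz = resample_hz,
                 body_scale_reference = body_scale_reference,
                 crop_before_s = crop_before_s,
                 crop_after_s = crop_after_s,
                 interp = interp,
                 onset_threshold = onset_threshold),
            class = "preprocess_config")
}

# Frames regarded as "address" before segmentation has run: the first 10%
# (at least 2 frames). Breaks the circularity between normalization /
# alignment (which want an address reference) and phase detection (which
# wants normalized input).
address_reference_idx <- function(seq, seg = NULL) {
  if (!is.null(seg)) {
    b <- seg$boundaries
    return(seq.int(b[1], b[2] - 1L))
  }
  seq_len(max(2L, ceiling(length(seq$time) * 0.10)))
}

#' Normalize a pose sequence by body scale
#'
#' Divides all coordinates by the reference scale `s*`, the mean left-right
#' shoulder distance over the address reference (first 10% of frames when no
#' segmentation is supplied, otherwise the detected address phase), so that
#' shoulder width becomes ~1 and skeletons of different sizes and camera
#' distances are comparable. Translation is untouched. Idempotent up to
#' numerical noise: re-normalizing changes coordinates by the ratio of an
#' already-unit shoulder width.
#'
#' @param seq a [pose_sequence()] in pixel units.
#' @param seg optional [phase_segmentation()] giving the address phase.
#' @return The sequence with `units = "body_scale"`.
#' @export
normalize_body_scale <- function(seq, seg = NULL) {
  validate_pose_sequence(seq)
  idx <- address_reference_idx(seq, seg)
  dx <- seq$x[idx, "left_shoulder"] - seq$x[idx, "right_shoulder"]
  dy <- seq$y[idx, "left_shoulder"] - seq$y[idx, "right_shoulder"]
  s_star <- mean(sqrt(dx^2 + dy^2))
  diag_ref <- sqrt(diff(range(seq$x))^2 + diff(range(seq$y))^2)
  if (!is.finite(s_star) || s_star < 1e-6 * max(diag_ref, 1))
    stop("degenerate skeleton: shoulder reference scale is ~0", call. = FALSE)
  out <- seq
  out$x <- seq$x / s_star
  out$y <- seq$y / s_star
  out$units <- "body_scale"
  out
}

#' Smooth every joint trajectory of a sequence
#'
#' Applies the centered shrunken-window moving average of
#' [smooth_moving_average()] to each joint's x and y series independently.
#'
#' @param seq a [pose_sequence()].
#' @param window odd window length in frames.
#' @return The smoothed sequence.
#' @export
smooth_pose_sequence <- function(seq, window = 5L) {
  out <- seq
  out$x <- apply(seq$x, 2, moving_average_vec, window = check_odd(window))
  out$y <- apply(seq$y, 2, moving_average_vec, window = as.integer(window))
  dimnames(out$x) <- dimnames(seq$x)
  dimnames(out$y) <- dimnames(seq$y)
  out
}

check_odd <- function(window) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("smoothing window must be an odd count >= 1, got ", window,
         call. = FALSE)
  window
}

# Smoothed lead-wrist speed in body-scale units per *frame* (the onset
# threshold is quoted per frame at 30 fps and rescaled by 30/fps).
lead_wrist_speed <- function(seq, window = 5L) {
  w <- lead_joint("wrist", seq$handedness)
  xs <- moving_average_vec(seq$x[, w], check_odd(window))
  ys <- moving_average_vec(seq$y[, w], as.integer(window))
  d <- sqrt(diff(xs)^2 + diff(ys)^2)
  c(d[1], d)  # per-frame displacement, first frame duplicated
}

onset_threshold_per_frame <- function(cfg, fps) {
  cfg$onset_threshold * (30 / fps)
}

# First index where speed exceeds `thr` for >= `sustain` consecutive frames.
first_sustained_exceedance <- function(speed, thr, sustain = 3L) {
  above <- speed > thr
  if (!any(above)) return(NA_integer_)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= sustain)
  if (!length(ok)) return(NA_integer_)
  starts[ok[1]]
}

#' Crop a recording to the swing window
#'
#' Detects the swing onset — the first time the smoothed lead-wrist speed
#' exceeds the onset threshold for at least 3 consecutive frames — and
#' returns the frames from `crop_before_s` before to `crop_after_s` after it,
#' clamped to the clip bounds. Intended for trimming long practice-range
#' recordings down to analysis clips.
#'
#' @param seq a body-scale [pose_sequence()] (pixel input is normalized
#'   internally for detection but returned in its original units).
#' @param cfg a [preprocess_config()].
#' @return The cropped [pose_sequence()].
#' @export
crop_swing_window <- function(seq, cfg = preprocess_config()) {
  validate_pose_sequence(seq)
  det <- if (seq$units == "pixels") normalize_body_scale(seq) else seq
  speed <- lead_wrist_speed(det, cfg$smoothing_window)
  thr <- onset_threshold_per_frame(cfg, seq$fps)
  onset <- first_sustained_exceedance(speed, thr)
  if (is.na(onset))
    stop("no swing detected: lead-wrist speed never exceeds threshold",
         call. = FALSE)
  t_on <- seq$time[onset]
  keep <- which(seq$time >= t_on - cfg$crop_before_s &
                  seq$time <= t_on + cfg$crop_after_s)
  subset_frames(seq, keep)
}

#' Align two sequences at the address posture
#'
#' Translates each body-scale sequence so that its mean mid-hip position over
#' the address phase sits at the origin; relative geometry within each clip is
#' unchanged. This synchronizes the starting posture of the two swings before
#' dynamic comparison, and makes the downstream comparison invariant to where
#' each player stood in the image.
#'
#' @param seqA,seqB body-scale [pose_sequence()] objects.
#' @param segA,segB optional segmentations locating each address phase
#'   (first 10% of frames used otherwise).
#' @return A list of the two aligned sequences.
#' @export
align_address <- function(seqA, seqB, segA = NULL, segB = NULL) {
  list(center_address(seqA, segA), center_address(seqB, segB))
}

center_address <- function(seq, seg = NULL) {
  if (!has_joints(seq, c("left_hip", "right_hip")))
    stop("address alignment requires both hip joints", call. = FALSE)
  idx <- address_reference_idx(seq, seg)
  cx <- mean(midpoint_x(seq, "left_hip", "right_hip")[idx])
  cy <- mean(midpoint_y(seq, "left_hip", "right_hip")[idx])
  out <- seq
  out$x <- seq$x - cx
  out$y <- seq$y - cy
  out
}

#' Run the standard preprocessing + segmentation pipeline on one clip
#'
#' Convenience wrapper applying, in order: body-scale normalization (if in
#' pixels), moving-average smoothing, swing-window cropping (only when the
#' clip is longer than the crop window — shorter clips are treated as already
#' cropped), phase detection, and address centering against the detected
#' address phase.
#'
#' @param seq a [pose_sequence()].
#' @param cfg a [preprocess_config()].
#' @return A `prepared_swing` list with elements `seq` (normalized, smoothed,
#'   cropped, address-centered sequence), `seg` ([phase_segmentation()]), and
#'   `basic` (the same sequence before address centering, used by baselines
#'   that are deliberately translation-sensitive).
#' @export
prepare_swing <- function(seq, cfg = preprocess_config()) {
  validate_pose_sequence(seq)
  if (seq$units == "pixels") seq <- normalize_body_scale(seq)
  raw <- seq
  seq <- smooth_pose_sequence(seq, cfg$smoothing_window)
  dur <- seq$time[length(seq$time)] - seq$time[1]
  if (dur > cfg$crop_before_s + cfg$crop_after_s) {
    seq <- crop_pipeline(seq, cfg)
    raw <- subset_frames(raw, match(round(seq$time, 9), round(raw$time, 9)))
  }
  seg <- detect_phases(seq, cfg, smoothed = TRUE)
  structure(list(seq = center_address(seq, seg), seg = seg, basic = seq,
                 raw = raw),
            class = "prepared_swing")
}

# Pipeline crop for recordings longer than the analysis window: anchored at
# the lead-wrist speed *peak* (mid-downswing), so 2 s before covers address
# and backswing and 1 s after covers follow-through and finish. The
# first-exceedance onset of crop_swing_window marks the takeaway, which sits
# too early in the swing to anchor a window that must contain the finish.
crop_pipeline <- function(seq, cfg) {
  speed <- lead_wrist_speed(seq, window = 1L)  # seq already smoothed
  thr <- onset_threshold_per_frame(cfg, seq$fps)
  if (is.na(first_sustained_exceedance(speed, thr)))
    stop("no swing detected: lead-wrist speed never exceeds threshold",
         call. = FALSE)
  t_peak <- seq$time[which.max(speed)]
  keep <- which(seq$time >= t_peak - cfg$crop_before_s &
                  seq$time <= t_peak + cfg$crop_after_s)
  subset_frames(seq, keep)
}
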