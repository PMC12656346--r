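#' Canonical swing phase names, in temporal order.
#' @export
phase_names <- c("address", "takeaway", "half", "top", "impact",
                 "release", "finish")

#' Phase segmentation of a swing clip
#'
#' Eight strictly increasing frame indices `b1 < b2 < ... < b8` partition the
#' clip into the seven canonical phases: phase *k* spans the half-open frame
#' interval `[b_k, b_{k+1})` (1-based; `b1 = 1` and `b8 = n + 1` for a clip
#' that is segmented end to end). Every phase is non-empty by construction.
#'
#' @param boundaries integer vector of 8 strictly increasing 1-based frame
#'   indices.
#' @param n_frames optional clip length, to bound-check against.
#' @return An object of class `phase_segmentation`.
#' @export
phase_segmentation <- function(boundaries, n_frames = NULL) {
  boundaries <- as.integer(boundaries)
  if (length(boundaries) != 8L)
    stop("need exactly 8 phase boundaries, got ", length(boundaries),
         call. = FALSE)
  if (any(diff(boundaries) < 1L))
    stop("validation error: phase boundaries must be strictly increasing ",
         "(every phase non-empty)", call. = FALSE)
  if (boundaries[1] < 1L)
    stop("first boundary must be >= 1", call. = FALSE)
  if (!is.null(n_frames) && boundaries[8] > n_frames + 1L)
    stop("validation error: boundaries exceed clip length", call. = FALSE)
  structure(list(boundaries = boundaries, phase_names = phase_names),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  b <- x$boundaries
  cat("<phase_segmentation>\n")
  for (k in 1:7)
    cat(sprintf("  %-8s frames [%d, %d)  (%d frames)\n",
                x$phase_names[k], b[k], b[k + 1], b[k + 1] - b[k]))
  invisible(x)
}

#' Detect the seven swing phases from kinematic cues
#'
#' Segments a swing using the smoothed lead-wrist trajectory (vertical
#' position `y_w`, per-frame speed `v_w`) and the per-frame lead-shoulder
#' height as reference, in image coordinates (y down, so "above shoulder"
#' means `y_w <= y_shoulder`):
#'
#' * **takeaway onset** — first sustained (>= 3 frames) `v_w` above the onset
#'   threshold;
#' * **half onset** — first backswing frame with the wrist at or above
#'   shoulder height;
#' * **top** — the contiguous low-speed region (`v_w` below half the onset
#'   threshold) around the wrist's highest point between the half onset and
#'   the downswing speed maximum;
#' * **impact** — the wrist's lowest point (global y maximum) after the top
#'   region;
#' * **release end** — first post-impact frame with the wrist back above
#'   shoulder height; the finish phase runs to the clip end.
#'
#' Extremum ties are broken by the earliest frame. Left-handed clips are
#' mirrored in x before detection (frame indices are unaffected), so one code
#' path serves both handednesses.
#'
#' @param seq a [pose_sequence()]; pixel input is body-scale normalized
#'   internally.
#' @param cfg a [preprocess_config()] (onset threshold, smoothing window).
#' @param smoothed set `TRUE` if `seq` is already moving-average smoothed to
#'   skip re-smoothing.
#' @return A [phase_segmentation()].
#' @export
detect_phases <- function(seq, cfg = preprocess_config(), smoothed = FALSE) {
  validate_pose_sequence(seq)
  if (seq$units == "pixels") seq <- normalize_body_scale(seq)
  if (!smoothed) seq <- smooth_pose_sequence(seq, cfg$smoothing_window)
  if (seq$handedness == "left")
    seq <- mirror_pose_sequence(seq)  # indices unaffected by mirroring
  n <- length(seq$time)
  fail <- function(event)
    stop("segmentation failed: event '", event, "' not found", call. = FALSE)

  yw <- seq$y[, "left_wrist"]
  ysh <- seq$y[, "left_shoulder"]
  v <- lead_wrist_speed(seq, window = 1L)  # seq already smoothed
  thr <- onset_threshold_per_frame(cfg, seq$fps)
  thr_top <- 0.5 * thr

  e_takeaway <- first_sustained_exceedance(v, thr)
  if (is.na(e_takeaway) || e_takeaway < 2L) fail("takeaway")

  half_cand <- which(yw <= ysh & seq_len(n) >= e_takeaway)
  if (!length(half_cand)) fail("half")
  e_half <- half_cand[1]
  if (e_half <= e_takeaway) fail("half")

  v_max <- (e_half - 1L) + which.max(v[e_half:n])
  e_top <- (e_half - 1L) + which.min(yw[e_half:v_max])

  low <- v < thr_top
  b_top_start <- e_top
  while (b_top_start > 1L && low[b_top_start - 1L]) b_top_start <- b_top_start - 1L
  b_top_end <- e_top  # last low-speed frame of the region
  while (b_top_end < n && low[b_top_end + 1L]) b_top_end <- b_top_end + 1L
  if (!low[e_top]) { b_top_start <- e_top; b_top_end <- e_top }
  b4 <- max(b_top_start, e_half + 1L)      # top start (keeps half non-empty)
  b5 <- max(b_top_end + 1L, b4 + 1L)       # impact-phase start
  if (b5 > n - 1L) fail("top")

  e_impact <- (b5 - 1L) + which.max(yw[b5:n])
  if (e_impact <= b5) fail("impact")

  rel_cand <- which(yw <= ysh & seq_len(n) > e_impact)
  if (!length(rel_cand)) fail("release")
  e_release <- rel_cand[1]
  if (e_release > n) fail("release")

  b <- c(1L, e_takeaway, e_half, b4, b5, e_impact, e_release, n + 1L)
  if (any(diff(b) < 1L))
    stop("segmentation failed: detected events out of order (",
         paste(b, collapse = ", "), ")", call. = FALSE)
  phase_segmentation(b, n_frames = n)
}

#' Slice a clip into its seven phases
#'
#' The slices are disjoint, cover the clip exactly (their concatenation
#' reproduces it), and carry their phase name as the `phase` attribute.
#'
#' @param seq a [pose_sequence()].
#' @param seg a [phase_segmentation()] valid for `seq`.
#' @return A named list of 7 `pose_sequence` slices.
#' @export
phase_slices <- function(seq, seg) {
  stopifnot(inherits(seg, "phase_segmentation"))
  n <- length(seq$time)
  b <- seg$boundaries
  if (b[8] != n + 1L || b[1] != 1L)
    stop("validation error: segmentation does not span the clip", call. = FALSE)
  if (any(diff(b) < 1L))
    stop("validation error: empty phase in segmentation", call. = FALSE)
  out <- vector("list", 7L)
  names(out) <- seg$phase_names
  for (k in 1:7) {
    sl <- subset_frames(seq, seq.int(b[k], b[k + 1] - 1L))
    attr(sl, "phase") <- seg$phase_names[k]
    out[[k]] <- sl
  }
  out
}
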