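#' Synthetic swing style
#'
#' Parameter set describing one player's swing for the synthetic generator.
#' The defaults emulate the reference dataset's clip geometry: a 3 s,
#' 90-frame side-view clip at 30 fps containing a full seven-phase swing,
#' with the moving phases (takeaway through release) spanning 1.25 s and
#' static address/finish bookends.
#'
#' @param phase_durations seven positive phase durations in seconds
#'   (address, takeaway, half, top, impact, release, finish); defaults
#'   `c(0.9, 0.3, 0.25, 0.15, 0.25, 0.3, 0.85)`, summing to 3 s.
#' @param arc_radius wrist arc radius about the shoulder pivot, in body-scale
#'   units (shoulder width = 1); default 1.8.
#' @param top_height wrist y at the top of the backswing relative to the
#'   shoulder pivot, image-y-down (negative = above the shoulders); default
#'   -1.6. Magnitudes above `0.98 * arc_radius` are clamped.
#' @param plane_offset signed x shift of the downswing (and follow-through)
#'   hand path relative to the backswing path, in body-scale units; negative
#'   values give the pro-like pattern (downswing inside/below the backswing),
#'   positive the amateur-like one. Default -0.08.
#' @param spine_sway_amp amplitude in degrees of the sinusoidal spine-angle
#'   oscillation around the forward lean; default 2.
#' @param spine_lean baseline forward spine lean in degrees; default 12.
#' @param tempo_ratio optional backswing:downswing duration ratio; when
#'   supplied, the impact-phase duration is rescaled to
#'   `(takeaway + half + top) / tempo_ratio`. `NULL` (default) leaves
#'   `phase_durations` authoritative (default ratio 2.8).
#' @param noise_sigma standard deviation of the i.i.d. Gaussian jitter added
#'   to every coordinate, in body-scale units; default 0.01, about the
#'   pose-estimator jitter the smoothing stage targets.
#' @param seed integer seed making the clip fully deterministic.
#' @return A `swing_style` list.
#' @export
swing_style <- function(phase_durations = c(0.9, 0.3, 0.25, 0.15,
                                            0.25, 0.3, 0.85),
                        arc_radius = 1.8,
                        top_height = -1.6,
                        plane_offset = -0.08,
                        spine_sway_amp = 2,
                        spine_lean = 12,
                        tempo_ratio = NULL,
                        noise_sigma = 0.01,
                        seed = 1L) {
  if (length(phase_durations) != 7L || any(phase_durations <= 0))
    stop("phase_durations must be 7 positive values", call. = FALSE)
  if (arc_radius <= 0) stop("arc_radius must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (!is.null(tempo_ratio)) {
    if (tempo_ratio <= 0) stop("tempo_ratio must be positive", call. = FALSE)
    phase_durations[5] <- sum(phase_durations[2:4]) / tempo_ratio
  }
  structure(list(phase_durations = as.numeric(phase_durations),
                 arc_radius = as.numeric(arc_radius),
                 top_height = as.numeric(top_height),
                 plane_offset = as.numeric(plane_offset),
                 spine_sway_amp = as.numeric(spine_sway_amp),
                 spine_lean = as.numeric(spine_lean),
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "swing_style")
}

# Evaluate code under a local RNG seed without disturbing the caller's
# random stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Cosine-eased progress: s in [0,1] -> [0,1], zero velocity at both ends.
ease <- function(s) (1 - cos(pi * pmin(pmax(s, 0), 1))) / 2

#' Generate a synthetic side-view swing clip
#'
#' Builds a deterministic keypoint sequence for one swing: a static lower
#' body, a trunk whose spine angle oscillates about a forward lean, and
#' wrists following a circular arc about the (baseline-lean) shoulder pivot.
#' Within each moving phase the arc angle progresses with cosine-eased
#' angular velocity, so the top of the swing is a genuine low-speed reversal
#' and the downswing contains the speed maximum — the cues the phase detector
#' keys on. The downswing and follow-through hand path is shifted in x by
#' `plane_offset` (eased in over the first third of the downswing). Gaussian
#' jitter of s.d. `noise_sigma` is added to every coordinate under the
#' style's seed. Ground-truth phase boundaries are recorded at the parametric
#' phase transitions.
#'
#' @param style a [swing_style()].
#' @param fps frame rate (default 30).
#' @param handedness `"right"` (default) or `"left"`; left-handed clips are
#'   the exact x-mirror (with side labels swapped) of the right-handed
#'   construction.
#' @param clip_id,player_id identifiers stamped on the sequence.
#' @param units `"pixels"` (default; body units mapped at 100 px per unit
#'   onto a nominal 960x540 frame) or `"body_scale"`.
#' @return A `synthetic_clip` list: `sequence` (a [pose_sequence()]),
#'   `truth_boundaries` (8 ordered 1-based frame indices), `style`, and
#'   `px_per_unit`.
#' @export
generate_swing <- function(style, fps = 30, handedness = c("right", "left"),
                           clip_id = "synthetic", player_id = "synthetic",
                           units = c("pixels", "body_scale")) {
  stopifnot(inherits(style, "swing_style"))
  handedness <- match.arg(handedness)
  units <- match.arg(units)
  d <- style$phase_durations
  Tk <- cumsum(c(0, d))           # 8 phase-transition times
  T_total <- Tk[8]
  n <- as.integer(floor(T_total * fps + 1 - 1e-9))
  t <- (seq_len(n) - 1) / fps
  truth <- c(vapply(Tk[1:7], function(Tb)
    as.integer(ceiling(Tb * fps + 1 - 1e-9)), integer(1)), n + 1L)

  # arc angle per phase: address 15deg hold; up through 90 (shoulder height)
  # to the top angle; hold; back down through 0 (impact, lowest point); to
  # -90 (release end, shoulder height) and on to -150 (finish pose).
  r <- style$arc_radius
  top_h <- sign(style$top_height) * min(abs(style$top_height), 0.98 * r)
  phi_top <- acos(top_h / r) * 180 / pi
  phi_bnd <- c(15, 15, 90, phi_top, phi_top, 0, -90, -150)
  phase_of <- pmin(findInterval(t, Tk[2:8]) + 1L, 7L)
  s_in <- (t - Tk[phase_of]) / d[phase_of]
  phi_deg <- phi_bnd[phase_of] +
    (phi_bnd[phase_of + 1L] - phi_bnd[phase_of]) * ease(s_in)
  phi <- phi_deg * pi / 180

  # trunk: mid-hip fixed, spine angle = lean + sway oscillation
  lean <- style$spine_lean * pi / 180
  alpha <- lean + style$spine_sway_amp * pi / 180 * sin(2 * pi * t / T_total)
  hip_c <- c(0, 1.5)
  L <- 1.5
  msh_x <- hip_c[1] + L * sin(alpha)
  msh_y <- hip_c[2] - L * cos(alpha)
  pivot <- c(hip_c[1] + L * sin(lean), hip_c[2] - L * cos(lean))

  # downswing plane offset, eased in over the first 30% of the impact phase
  off <- numeric(n)
  imp <- phase_of == 5L
  off[imp] <- style$plane_offset * ease(pmin(s_in[imp] / 0.3, 1))
  off[phase_of > 5L] <- style$plane_offset

  wl_x <- pivot[1] + r * sin(phi) + off
  wl_y <- pivot[2] + r * cos(phi)
  # trailing hand slightly further down the grip
  dirx <- sin(phi); diry <- cos(phi)
  wr_x <- wl_x + 0.05 * dirx
  wr_y <- wl_y + 0.05 * diry
  # elbows midway along the (actual) arm line, with a fixed outward bend
  mid_ex <- pivot[1] + 0.5 * (wl_x - pivot[1])
  mid_ey <- pivot[2] + 0.5 * (wl_y - pivot[2])
  perp_x <- -diry; perp_y <- dirx
  el_x <- mid_ex + 0.12 * perp_x; el_y <- mid_ey + 0.12 * perp_y
  er_x <- mid_ex - 0.12 * perp_x; er_y <- mid_ey - 0.12 * perp_y

  joints <- core_joints
  X <- matrix(0, n, length(joints), dimnames = list(NULL, joints))
  Y <- X
  X[, "nose"] <- hip_c[1] + (L + 0.6) * sin(alpha)
  Y[, "nose"] <- hip_c[2] - (L + 0.6) * cos(alpha)
  X[, "left_shoulder"] <- msh_x - 0.5;  Y[, "left_shoulder"] <- msh_y
  X[, "right_shoulder"] <- msh_x + 0.5; Y[, "right_shoulder"] <- msh_y
  X[, "left_elbow"] <- el_x;  Y[, "left_elbow"] <- el_y
  X[, "right_elbow"] <- er_x; Y[, "right_elbow"] <- er_y
  X[, "left_wrist"] <- wl_x;  Y[, "left_wrist"] <- wl_y
  X[, "right_wrist"] <- wr_x; Y[, "right_wrist"] <- wr_y
  X[, "left_hip"] <- hip_c[1] - 0.35;  Y[, "left_hip"] <- hip_c[2]
  X[, "right_hip"] <- hip_c[1] + 0.35; Y[, "right_hip"] <- hip_c[2]
  X[, "left_knee"] <- hip_c[1] - 0.35;  Y[, "left_knee"] <- hip_c[2] + 1.0
  X[, "right_knee"] <- hip_c[1] + 0.35; Y[, "right_knee"] <- hip_c[2] + 1.0
  X[, "left_ankle"] <- hip_c[1] - 0.35;  Y[, "left_ankle"] <- hip_c[2] + 1.9
  X[, "right_ankle"] <- hip_c[1] + 0.35; Y[, "right_ankle"] <- hip_c[2] + 1.9

  if (style$noise_sigma > 0) {
    with_local_seed(style$seed, {
      X <- X + matrix(stats::rnorm(n * ncol(X), 0, style$noise_sigma),
                      n, ncol(X))
      Y <- Y + matrix(stats::rnorm(n * ncol(Y), 0, style$noise_sigma),
                      n, ncol(Y))
    })
    colnames(X) <- joints; colnames(Y) <- joints
  }

  px <- 100
  if (units == "pixels") {
    X <- X * px + 480
    Y <- Y * px + 190
  }
  seq <- pose_sequence(time = t, x = X, y = Y, fps = fps, units = units,
                       handedness = "right", clip_id = clip_id,
                       player_id = player_id)
  if (handedness == "left") seq <- mirror_pose_sequence(seq)
  structure(list(sequence = seq, truth_boundaries = truth, style = style,
                 px_per_unit = if (units == "pixels") px else 1),
            class = "synthetic_clip")
}

#' @export
print.synthetic_clip <- function(x, ...) {
  cat("<synthetic_clip>\n")
  print(x$sequence)
  cat("  truth boundaries:", paste(x$truth_boundaries, collapse = ", "), "\n")
  invisible(x)
}

#' Sample repeated clips from one player
#'
#' Draws `n_clips` clips whose style parameters are perturbed
#' multiplicatively by seeded Gaussian factors of standard deviation
#' `within_player_sd` around the base style (phase durations, arc radius,
#' top height, plane offset and sway amplitude; factors clamped to
#' \[0.5, 1.5\]). Clips from one base are therefore statistically closer to
#' each other than to clips from a different base.
#'
#' @param base a [swing_style()].
#' @param n_clips number of clips (>= 1).
#' @param within_player_sd fractional within-player variation in \[0, 0.5).
#' @param seed integer seed; each clip also receives a derived jitter seed.
#' @param player_id player label stamped on the clips.
#' @param fps frame rate.
#' @return A list of `synthetic_clip` objects.
#' @export
sample_player <- function(base, n_clips, within_player_sd = 0.05,
                          seed = 1L, player_id = "player", fps = 30) {
  stopifnot(inherits(base, "swing_style"), n_clips >= 1,
            within_player_sd >= 0, within_player_sd < 0.5)
  with_local_seed(seed, {
    lapply(seq_len(n_clips), function(i) {
      f <- function(k = 1) pmin(pmax(stats::rnorm(k, 1, within_player_sd),
                                     0.5), 1.5)
      st <- base
      st$phase_durations <- base$phase_durations * f(7)
      st$arc_radius <- base$arc_radius * f()
      st$top_height <- base$top_height * f()
      st$plane_offset <- base$plane_offset * f()
      st$spine_sway_amp <- base$spine_sway_amp * f()
      st$seed <- (base$seed + 7919L * i) %% .Machine$integer.max
      generate_swing(st, fps = fps,
                     clip_id = sprintf("%s_c%02d", player_id, i),
                     player_id = player_id)
    })
  })
}

#' Inject a wrist-path perturbation into a clip
#'
#' Adds a smooth `amplitude * sin^2` bump (in body-scale units) to both
#' wrists' x coordinates over a time window — by default the clip's
#' impact-through-release region, where hand speed is high, so the
#' segmentation cues (address stillness, the low-speed top) are untouched.
#' Used to verify that the integral dissimilarity grows monotonically with a
#' controlled path difference.
#'
#' @param clip a `synthetic_clip`.
#' @param amplitude bump height in body-scale units (>= 0).
#' @param window optional `c(t_start, t_end)` in seconds; default the truth
#'   impact..release region.
#' @return The perturbed `synthetic_clip`.
#' @export
perturb_wrist_path <- function(clip, amplitude, window = NULL) {
  stopifnot(inherits(clip, "synthetic_clip"), amplitude >= 0)
  seq <- clip$sequence
  if (is.null(window)) {
    b <- clip$truth_boundaries
    window <- c(seq$time[b[5]], seq$time[min(b[7], length(seq$time))])
  }
  u <- (seq$time - window[1]) / (window[2] - window[1])
  bump <- ifelse(u > 0 & u < 1, amplitude * sin(pi * u)^2, 0)
  bump <- bump * clip$px_per_unit
  for (j in c("left_wrist", "right_wrist"))
    seq$x[, j] <- seq$x[, j] + bump
  out <- clip
  out$sequence <- seq
  out
}

#' Build the standard synthetic benchmark cohort
#'
#' Eight fixed player styles spanning realistic ranges of arc radius, top
#' height, swing-plane offset, spine sway and tempo, each contributing
#' `clips_per_style` clips drawn with [sample_player()]. The resulting cohort
#' (default 32 clips) stands in for a multi-player side-view dataset in the
#' discrimination experiments: clips sharing a style play the role of repeat
#' swings by one player.
#'
#' @param clips_per_style clips per player style (default 4).
#' @param within_player_sd within-player parameter variation (default 0.05).
#' @param noise_sigma coordinate jitter s.d. in body-scale units (default
#'   0.01).
#' @param seed integer master seed; every clip's jitter and parameter draw
#'   derives from it.
#' @param fps frame rate (default 30).
#' @return A list of `synthetic_clip`s with `player_id`s `style1`..`style8`.
#' @export
benchmark_clips <- function(clips_per_style = 4L, within_player_sd = 0.05,
                            noise_sigma = 0.01, seed = 1L, fps = 30) {
  d0 <- c(0.9, 0.3, 0.25, 0.15, 0.25, 0.3, 0.85)
  styles <- list(
    swing_style(d0, arc_radius = 1.80, top_height = -1.60,
                plane_offset = -0.08, spine_sway_amp = 2.0,
                noise_sigma = noise_sigma),
    swing_style(d0, arc_radius = 1.50, top_height = -1.35,
                plane_offset = -0.05, spine_sway_amp = 3.0,
                noise_sigma = noise_sigma),
    swing_style(d0, arc_radius = 2.00, top_height = -1.75,
                plane_offset = -0.10, spine_sway_amp = 1.5,
                noise_sigma = noise_sigma),
    swing_style(d0, arc_radius = 1.70, top_height = -1.50,
                plane_offset = 0.08, spine_sway_amp = 5.0,
                noise_sigma = noise_sigma),
    swing_style(replace(d0, 5, 0.32), arc_radius = 1.60, top_height = -1.25,
                plane_offset = 0.05, spine_sway_amp = 6.0,
                noise_sigma = noise_sigma),
    swing_style(replace(d0, 5, 0.20), arc_radius = 1.90, top_height = -1.65,
                plane_offset = -0.02, spine_sway_amp = 2.5,
                noise_sigma = noise_sigma),
    swing_style(replace(d0, 3, 0.32), arc_radius = 1.75, top_height = -1.55,
                plane_offset = 0.10, spine_sway_amp = 4.0,
                noise_sigma = noise_sigma),
    swing_style(replace(d0, 2, 0.24), arc_radius = 1.85, top_height = -1.45,
                plane_offset = -0.06, spine_sway_amp = 3.5,
                noise_sigma = noise_sigma))
  clips <- list()
  for (k in seq_along(styles)) {
    st <- styles[[k]]
    st$seed <- (seed + 104729L * k) %% .Machine$integer.max
    clips <- c(clips, sample_player(st, clips_per_style,
                                    within_player_sd = within_player_sd,
                                    seed = st$seed,
                                    player_id = paste0("style", k),
                                    fps = fps))
  }
  clips
}
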