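#' Joint vocabularies
#'
#' Semantic joint labels used throughout the package. Sequences may carry any
#' subset of the 33 BlazePose landmarks (plus extensions), but a valid
#' [pose_sequence()] must always contain the minimal required set used by
#' normalization, alignment and phase detection.
#'
#' @name joints
NULL

#' The 33 BlazePose landmark names, in canonical model order.
#' @rdname joints
#' @export
blazepose_landmarks <- c(
  "nose",
  "left_eye_inner", "left_eye", "left_eye_outer",
  "right_eye_inner", "right_eye", "right_eye_outer",
  "left_ear", "right_ear",
  "mouth_left", "mouth_right",
  "left_shoulder", "right_shoulder",
  "left_elbow", "right_elbow",
  "left_wrist", "right_wrist",
  "left_pinky", "right_pinky",
  "left_index", "right_index",
  "left_thumb", "right_thumb",
  "left_hip", "right_hip",
  "left_knee", "right_knee",
  "left_ankle", "right_ankle",
  "left_heel", "right_heel",
  "left_foot_index", "right_foot_index"
)

#' Joints that every valid pose sequence must carry.
#' @rdname joints
#' @export
required_joints <- c(
  "left_shoulder", "right_shoulder",
  "left_hip", "right_hip",
  "left_wrist", "right_wrist"
)

#' The 13-joint core body set used by the synthetic generator and defaults.
#' @rdname joints
#' @export
core_joints <- c(
  "nose",
  "left_shoulder", "right_shoulder",
  "left_elbow", "right_elbow",
  "left_wrist", "right_wrist",
  "left_hip", "right_hip",
  "left_knee", "right_knee",
  "left_ankle", "right_ankle"
)

# Lead side of the body: the side nearer the target (left for right-handed).
lead_side <- function(handedness) {
  if (identical(handedness, "left")) "right" else "left"
}

lead_joint <- function(joint_base, handedness) {
  paste(lead_side(handedness), joint_base, sep = "_")
}
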