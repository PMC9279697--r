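# Canonical Kinect V2 joint enumeration and skeleton topology.

#' Canonical Kinect V2 joint names
#'
#' The fixed, ordered 25-joint enumeration of the Kinect V2 SDK
#' (`JointType`), from `SpineBase` to `ThumbRight`. All on-disk and in-memory
#' skeleton containers in this package use exactly this order; files with a
#' different per-frame joint order are rejected rather than reordered.
#'
#' @return Character vector of length 25.
#' @export
#' @examples
#' kinect_joints()
kinect_joints <- function() {
  c(
    "SpineBase", "SpineMid", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
    "HipRight", "KneeRight", "AnkleRight", "FootRight",
    "SpineShoulder",
    "HandTipLeft", "ThumbLeft", "HandTipRight", "ThumbRight"
  )
}

#' Skeleton bone list (parent-child joint pairs)
#'
#' The 24 bones connecting the 25 Kinect V2 joints, used for bone-length
#' conservation checks on simulated motion.
#'
#' @return A tibble with columns `from` and `to` (joint names).
#' @export
kinect_bones <- function() {
  tibble::tribble(
    ~from,            ~to,
    "SpineBase",      "SpineMid",
    "SpineMid",       "SpineShoulder",
    "SpineShoulder",  "Neck",
    "Neck",           "Head",
    "SpineShoulder",  "ShoulderLeft",
    "ShoulderLeft",   "ElbowLeft",
    "ElbowLeft",      "WristLeft",
    "WristLeft",      "HandLeft",
    "HandLeft",       "HandTipLeft",
    "WristLeft",      "ThumbLeft",
    "SpineShoulder",  "ShoulderRight",
    "ShoulderRight",  "ElbowRight",
    "ElbowRight",     "WristRight",
    "WristRight",     "HandRight",
    "HandRight",      "HandTipRight",
    "WristRight",     "ThumbRight",
    "SpineBase",      "HipLeft",
    "HipLeft",        "KneeLeft",
    "KneeLeft",       "AnkleLeft",
    "AnkleLeft",      "FootLeft",
    "SpineBase",      "HipRight",
    "HipRight",       "KneeRight",
    "KneeRight",      "AnkleRight",
    "AnkleRight",     "FootRight"
  )
}

# Per-joint feature channel names in canonical order: 25 joints x
# (x, y, z, rx, ry, rz, rw) = 175 columns.
feature_channel_names <- function() {
  channels <- c("x", "y", "z", "rx", "ry", "rz", "rw")
  as.vector(vapply(
    kinect_joints(),
    function(j) paste(j, channels, sep = "."),
    character(7)
  ))
}

# The six cued stimulus actions (five directives plus reset).
#' Stimulus task actions
#'
#' The scripted standing protocol consists of five audio-cued directives plus
#' a reset: lift both hands, lift the left hand, lift the right hand, turn
#' right, turn left, and return to rest.
#'
#' @return Character vector of the six action labels.
#' @export
stimulus_actions <- function() {
  c("LIFT_TWO_HANDS", "LIFT_LEFT", "LIFT_RIGHT",
    "TURN_RIGHT", "TURN_LEFT", "RESET")
}
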