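#' @import methods
#' @importFrom stats approx anova lm median pf pnorm pt qt rnorm rpois rexp
#'   runif sd setNames t.test var filter complete.cases
#' @importFrom utils write.table head tail
NULL

## Canonical joint vocabulary -------------------------------------------------

#' The 25 canonical skeleton joints
#'
#' The body-tracking SDK of the Kinect V2 sensor reports 25 named joints per
#' skeleton. \code{kinectJoints()} returns their canonical lower-snake-case
#' names in the package's fixed order; \code{analysisJoints()} returns the
#' 17-joint analysis subset used for seated subjects, in the row order used by
#' all report tables (trunk first, then left arm, right arm, left leg, right
#' leg, spine shoulder).
#'
#' Hands, hand tips, thumbs and feet are excluded from the analysis set: for
#' seated subjects not presenting the hand to the sensor these joints are
#' tracked too poorly to be usable, and the wrist (resp. ankle) is kept as the
#' distal representative of each limb.
#'
#' @return Character vector of joint names.
#' @examples
#' length(kinectJoints())    # 25
#' length(analysisJoints())  # 17
#' @export
kinectJoints <- function() .JOINTS_25

#' @rdname kinectJoints
#' @export
analysisJoints <- function() .JOINTS_17

.JOINTS_25 <- c(
  "spine_base", "spine_mid", "neck", "head",
  "left_shoulder", "left_elbow", "left_wrist", "left_hand",
  "right_shoulder", "right_elbow", "right_wrist", "right_hand",
  "left_hip", "left_knee", "left_ankle", "left_foot",
  "right_hip", "right_knee", "right_ankle", "right_foot",
  "spine_shoulder",
  "left_hand_tip", "left_thumb", "right_hand_tip", "right_thumb"
)

## Rejected for seated capture: the four hand-region joints per side and feet.
.JOINTS_REJECTED <- c(
  "left_hand", "right_hand",
  "left_hand_tip", "right_hand_tip",
  "left_thumb", "right_thumb",
  "left_foot", "right_foot"
)

## Report row order: trunk, left arm, right arm, hips/legs, spine shoulder.
.JOINTS_17 <- c(
  "spine_base", "spine_mid", "neck", "head",
  "left_shoulder", "left_elbow", "left_wrist",
  "right_shoulder", "right_elbow", "right_wrist",
  "left_hip", "left_knee", "left_ankle",
  "right_hip", "right_knee", "right_ankle",
  "spine_shoulder"
)

## Alias table mapping Kinect SDK JointType spellings onto the canon.
.JOINT_ALIASES <- c(
  SpineBase = "spine_base", SpineMid = "spine_mid", Neck = "neck",
  Head = "head",
  ShoulderLeft = "left_shoulder", ElbowLeft = "left_elbow",
  WristLeft = "left_wrist", HandLeft = "left_hand",
  ShoulderRight = "right_shoulder", ElbowRight = "right_elbow",
  WristRight = "right_wrist", HandRight = "right_hand",
  HipLeft = "left_hip", KneeLeft = "left_knee", AnkleLeft = "left_ankle",
  FootLeft = "left_foot",
  HipRight = "right_hip", KneeRight = "right_knee",
  AnkleRight = "right_ankle", FootRight = "right_foot",
  SpineShoulder = "spine_shoulder",
  HandTipLeft = "left_hand_tip", ThumbLeft = "left_thumb",
  HandTipRight = "right_hand_tip", ThumbRight = "right_thumb"
)

.TRACKING_STATES <- c("tracked", "inferred", "not_tracked")

## Normalize a vector of joint names: map SDK spellings, validate against the
## canon. Returns the canonical names; attributes bad indices on failure.
.normalizeJoints <- function(x) {
  x <- as.character(x)
  hit <- match(x, names(.JOINT_ALIASES))
  x[!is.na(hit)] <- .JOINT_ALIASES[hit[!is.na(hit)]]
  bad <- !(x %in% .JOINTS_25)
  structure(x, bad = which(bad))
}

#' Restrict a joint set to the analysis joints
#'
#' Drops the hand, hand-tip, thumb and foot joints of both sides; every other
#' canonical joint passes through. Applied to the full 25-joint canon this
#' yields the 17-joint analysis set.
#'
#' @param joints Character vector of canonical joint names (SDK spellings such
#'   as \code{"SpineBase"} are accepted and normalized).
#' @return Character vector, the input minus the rejected joints, in analysis
#'   row order.
#' @examples
#' length(selectAnalysisJoints(kinectJoints()))  # 17
#' selectAnalysisJoints(c("head"))
#' selectAnalysisJoints(c("left_hand_tip", "right_foot"))  # character(0)
#' @export
selectAnalysisJoints <- function(joints) {
  joints <- .normalizeJoints(joints)
  if (length(attr(joints, "bad")))
    stop("unknown joint name(s): ",
         paste(unique(joints[attr(joints, "bad")]), collapse = ", "))
  keep <- setdiff(as.character(joints), .JOINTS_REJECTED)
  .JOINTS_17[.JOINTS_17 %in% keep]
}
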