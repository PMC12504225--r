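# Canonical channel and joint naming for the 18-channel kinematic layout.

.kinematic_channels <- c(
  "Lankleflex", "Lanklepron", "Lhipabad", "Lhipflex", "Lhiprot", "Lkneeflex",
  "Pelvicobl", "Pelvicrot", "Pelvictil",
  "Rankleflex", "Ranklepron", "Rhipabad", "Rhipflex", "Rhiprot", "Rkneeflex",
  "Trunkflex", "Trunkrot", "Trunktilt"
)

# Sagittal-plane joints carrying moment labels, in the fixed reporting order.
.moment_joints <- c("LKneeFlex", "RKneeFlex", "LAnkleFlex", "RAnkleFlex",
                    "LHipFlex", "RHipFlex")

# angle channel feeding each moment joint
.moment_angle_channel <- c(
  LKneeFlex = "Lkneeflex", RKneeFlex = "Rkneeflex",
  LAnkleFlex = "Lankleflex", RAnkleFlex = "Rankleflex",
  LHipFlex = "Lhipflex", RHipFlex = "Rhipflex"
)

# left/right angle and moment pairs for per-joint fine-tuning
.joint_pairs <- list(
  knee  = list(angles = c("Lkneeflex", "Rkneeflex"),
               moments = c("LKneeFlex", "RKneeFlex")),
  ankle = list(angles = c("Lankleflex", "Rankleflex"),
               moments = c("LAnkleFlex", "RAnkleFlex")),
  hip   = list(angles = c("Lhipflex", "Rhipflex"),
               moments = c("LHipFlex", "RHipFlex"))
)

.speed_levels <- c("slow", "comfortable", "fast")

.age_groups <- c("3-6", "7-8", "9-10", "11-12", ">=13")
.age_group_counts <- c(11, 10, 15, 11, 8)  # study strata out of 55

#' Names of the 18 kinematic channels
#'
#' The fixed channel vocabulary used throughout the package: left/right ankle,
#' hip and knee angles plus pelvis and trunk orientation channels, in degrees.
#' @return Character vector of length 18.
#' @export
kinematic_channels <- function() .kinematic_channels

#' Names of the six sagittal joints carrying moment labels
#'
#' Order is fixed (left/right knee, ankle, hip) and used for moment traces and
#' the rows/columns of cross-joint matrices. Units are N·m/kg.
#' @return Character vector of length 6.
#' @export
moment_joints <- function() .moment_joints

#' Left/right angle-moment channel pairs for per-joint fine-tuning
#' @param joint One of `"knee"`, `"ankle"`, `"hip"`.
#' @return List with `angles` and `moments` character vectors (length 2).
#' @export
joint_pair <- function(joint = c("knee", "ankle", "hip")) {
  joint <- match.arg(joint)
  .joint_pairs[[joint]]
}
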