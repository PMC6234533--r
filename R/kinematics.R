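# Forward kinematics: compose the kinematic tree from a generalized
# coordinate vector. This R implementation is the readable reference; the
# compiled solver (src/) reproduces it bit-for-bit on the same model.

joint_rotation <- function(joint, q) {
  R <- diag(3)
  for (k in seq_len(ncol(joint$axes)))
    R <- R %*% rot_about(joint$axes[, k], q[[joint$coords[k]]])
  R
}

prescribed_translation <- function(joint, flexion) {
  if (is.null(joint$prescribed)) return(c(0, 0, 0))
  c(nat_spline_eval(joint$prescribed$ap, flexion),
    nat_spline_eval(joint$prescribed$si, flexion), 0)
}

#' Forward kinematics of the constrained model
#'
#' Computes world positions of every model marker and of the hip, knee,
#' ankle and toe joint centers for one pose, walking the tree from the
#' pelvis: the pelvis 6-DOF rigid transform, then per joint the rotations
#' about its axes plus (for the knee) the prescribed tibiofemoral
#' translation evaluated at the flexion angle.
#'
#' @param model a `constrained_model`.
#' @param q named numeric vector of length 20 (see [coord_names()]); mm
#'   for pelvis translations, degrees elsewhere.
#' @return A list with `markers` (n x 3 matrix, rownames = labels),
#'   `joint_centers` (8 x 3: hip/knee/ankle/mtp for right then left),
#'   and `segment_pose` (per segment a list with rotation `R` and origin
#'   `t` in the lab frame).
#' @export
#' @examples
#' m <- generic_model()
#' fk <- forward_kinematics(m, neutral_pose(m))
#' fk$joint_centers["hip_r", ]
forward_kinematics <- function(model, q) {
  cn <- coord_names(model)
  if (is.null(names(q))) names(q) <- cn
  stopifnot(all(cn %in% names(q)))
  b <- coord_bounds(model)
  bad <- which(q[cn] < b[, 1] - 1e-9 | q[cn] > b[, 2] + 1e-9)
  if (length(bad))
    stop(sprintf("coordinate out of bounds: %s", paste(cn[bad], collapse = ", ")))

  poses <- list()
  markers <- list()
  for (s in model$segments) {
    if (s$name == "pelvis") {
      R <- rot_about(c(0, 0, 1), q[["pelvis_tilt"]]) %*%
        rot_about(c(1, 0, 0), q[["pelvis_list"]]) %*%
        rot_about(c(0, 1, 0), q[["pelvis_rotation"]])
      t <- c(q[["pelvis_tx"]], q[["pelvis_ty"]], q[["pelvis_tz"]])
    } else {
      pp <- poses[[s$parent]]
      jt <- model$joints[[s$parent_joint]]
      Rj <- joint_rotation(jt, q)
      tp <- if (jt$type == "mobile_hinge")
        prescribed_translation(jt, q[[jt$coords[1]]]) else c(0, 0, 0)
      R <- pp$R %*% Rj
      t <- pp$t + as.vector(pp$R %*% (s$origin_in_parent)) + as.vector(R %*% tp)
    }
    poses[[s$name]] <- list(R = R, t = t)
    for (lab in names(s$markers))
      markers[[lab]] <- as.vector(R %*% s$markers[[lab]]) + t
  }

  jc <- rbind(
    hip_r = poses$thigh_r$t, knee_r = poses$shank_r$t,
    ankle_r = poses$foot_r$t, mtp_r = poses$toes_r$t,
    hip_l = poses$thigh_l$t, knee_l = poses$shank_l$t,
    ankle_l = poses$foot_l$t, mtp_l = poses$toes_l$t)
  colnames(jc) <- c("x", "y", "z")
  mk <- do.call(rbind, markers)
  colnames(mk) <- c("x", "y", "z")
  list(markers = mk, joint_centers = jc, segment_pose = poses)
}

# Static (single-frame) marker map at the neutral pose; used by the
# generator and for landmark distances during scaling.
neutral_markers <- function(model) {
  forward_kinematics(model, neutral_pose(model))$markers
}
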