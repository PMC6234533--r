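# Inverse kinematics, two ways: (1) constrained weighted least-squares fit
# of the whole chain to the markers, frame by frame (compiled
# Levenberg-Marquardt with warm starts); (2) unconstrained per-segment
# rigid-body pose fits (SVD) with floating-axis Euler decomposition.

# initial pose: align the pelvis to its 4 markers, joint angles neutral
initial_pose <- function(model, trial, frame = 1) {
  labs <- c("R.ASIS", "L.ASIS", "R.PSIS", "L.PSIS")
  local <- t(vapply(labs, function(l) model$segments$pelvis$markers[[l]],
                    numeric(3)))
  obs <- t(vapply(labs, function(l) trial$coords[frame, , l], numeric(3)))
  q0 <- neutral_pose(model)
  if (any(!is.finite(obs))) {
    q0["pelvis_ty"] <- 900
    return(q0)
  }
  tf <- segment_pose_svd(local, obs)
  ang <- decompose_zxy(tf$R)
  q0[c("pelvis_tx", "pelvis_ty", "pelvis_tz")] <- tf$t
  q0[c("pelvis_tilt", "pelvis_list", "pelvis_rotation")] <- ang
  q0
}

#' Constrained inverse kinematics
#'
#' Per frame, finds the generalized coordinates `q` minimizing the weighted
#' sum of squared distances between experimental and model marker
#' positions, subject to the model's joint constraints and coordinate
#' bounds. Frame 1 is initialized by aligning the pelvis to its markers
#' with all joint angles neutral; later frames warm-start from the
#' previous solution. All markers receive equal weight by default.
#'
#' @param model a (scaled) `constrained_model`.
#' @param trial a gap-free `marker_trial` (gapped samples are down-weighted
#'   to zero for their frames).
#' @param included_markers marker labels to track; defaults to every model
#'   marker present in the trial. Pelvis and shoe markers should always be
#'   included; any subset of the eight thigh/shank markers may be dropped
#'   (the distal foot markers keep each leg observable).
#' @param weights optional named non-negative weight per marker.
#' @param xtol,gtol,ftol,max_iter optimizer controls: coordinate-step,
#'   gradient and relative-cost tolerances and the iteration cap.
#' @return An `ik_result`: list with `q` (frames x 20 matrix of named
#'   coordinates), `residuals` (frames x markers Euclidean distance, mm;
#'   `NA` for untracked markers), `joint_centers` (3 x 8 x frames cube),
#'   `model_markers` (3 x markers x frames cube of model-predicted
#'   positions), `converged`, `iterations`, `weights`,
#'   `included_markers`.
#' @export
constrained_ik <- function(model, trial, included_markers = NULL,
                           weights = NULL, xtol = 1e-7, gtol = 1e-10,
                           ftol = 1e-10, max_iter = 100) {
  stopifnot(inherits(model, "constrained_model"), inherits(trial, "marker_trial"))
  labs <- model_markers(model)
  if (is.null(included_markers))
    included_markers <- intersect(labs, trial$labels)
  unknown <- setdiff(included_markers, labs)
  if (length(unknown))
    stop(sprintf("markers not in the model: %s", paste(unknown, collapse = ", ")))
  if (!all(included_markers %in% trial$labels))
    stop("included markers missing from the trial")

  w <- setNames(rep(0, length(labs)), labs)
  w[included_markers] <- 1
  if (!is.null(weights)) {
    if (any(weights < 0)) stop("weights must be non-negative")
    w[names(weights)] <- weights
  }

  pelvis_labs <- names(model$segments$pelvis$markers)
  if (sum(w[pelvis_labs] > 0) < 3)
    stop("observability error: the pelvis needs at least 3 markers")
  for (side in c("r", "l")) {
    S <- toupper(side)
    distal <- unlist(lapply(model$segments[paste0(c("thigh_", "shank_", "foot_", "toes_"), side)],
                            function(s) names(s$markers)))
    if (sum(w[distal] > 0) < 2)
      stop(sprintf("observability error: leg %s has no markers distal to the pelvis", S))
  }

  flat <- model_flat(model)
  cube <- trial_cube(trial, flat$labels)
  q0 <- initial_pose(model, trial)
  sol <- ik_solve_cpp(flat, cube, unname(w[flat$labels]), unname(q0),
                      flat$bounds, xtol, gtol, ftol, max_iter)
  colnames(sol$q) <- flat$coord_names
  colnames(sol$resid) <- flat$labels
  fk <- fk_batch_cpp(flat, sol$q)
  centers <- fk$seg_t[, -1, , drop = FALSE]  # drop pelvis origin
  dimnames(centers) <- list(c("x", "y", "z"),
                            c("hip_r", "knee_r", "ankle_r", "mtp_r",
                              "hip_l", "knee_l", "ankle_l", "mtp_l"), NULL)
  dimnames(fk$markers) <- list(c("x", "y", "z"), flat$labels, NULL)
  structure(list(q = sol$q, residuals = sol$resid,
                 joint_centers = centers, model_markers = fk$markers,
                 converged = as.logical(sol$converged),
                 iterations = as.integer(sol$iterations),
                 weights = w, included_markers = included_markers,
                 rate = trial$rate), class = "ik_result")
}

#' @export
print.ik_result <- function(x, ...) {
  cat(sprintf("<ik_result> %d frames, %d tracked markers, %d unconverged, mean residual %.3f mm\n",
              nrow(x$q), length(x$included_markers), sum(!x$converged),
              mean(x$residuals, na.rm = TRUE)))
  invisible(x)
}

#' Soft-tissue-artifact proxy: per-marker RMS of IK residuals
#'
#' The root-mean-square, over frames, of the Euclidean distance between
#' each experimentally measured marker trajectory and the model marker
#' trajectory reconstructed at the converged IK solution. With a full
#' marker set this is the standard proxy for soft-tissue artifact
#' magnitude.
#'
#' @param ik an `ik_result` from a full-marker-set fit.
#' @param trial the `marker_trial` the fit was run on (unused beyond a
#'   consistency check; residuals are stored in `ik`).
#' @return Named numeric vector: per-marker RMS (mm) for tracked markers.
#' @export
sta_proxy <- function(ik, trial = NULL) {
  stopifnot(inherits(ik, "ik_result"))
  if (!is.null(trial) && nrow(ik$q) != n_frames(trial))
    stop("ik result and trial disagree on frame count")
  r <- ik$residuals[, ik$included_markers, drop = FALSE]
  sqrt(colMeans(r^2, na.rm = TRUE))
}

#' Rigid-body pose from point correspondences (SVD method)
#'
#' Least-squares rigid transform `y ~ R x + t` between matched marker sets
#' by the cross-covariance SVD method, with the determinant correction
#' that guarantees a proper rotation (no reflection).
#'
#' @param local `n x 3` matrix of segment-frame marker positions (n >= 3,
#'   non-collinear).
#' @param observed `n x 3` matrix of corresponding lab-frame positions.
#' @return List with `R` (3x3 rotation, det +1), `t` (length-3
#'   translation) and `rms` (mm residual).
#' @export
segment_pose_svd <- function(local, observed) {
  local <- as.matrix(local); observed <- as.matrix(observed)
  stopifnot(ncol(local) == 3, all(dim(local) == dim(observed)), nrow(local) >= 3)
  cx <- colMeans(local); cy <- colMeans(observed)
  X <- sweep(local, 2, cx); Y <- sweep(observed, 2, cy)
  sx <- svd(X)$d
  if (sx[2] < 1e-9 * max(sx[1], 1))
    stop("degenerate marker configuration: markers are collinear")
  s <- svd(crossprod(X, Y))  # H = sum_i x_i y_i^T
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.vector(R %*% cx)
  fit <- sweep(local %*% t(R), 2, t, "+")
  list(R = R, t = t, rms = sqrt(mean(rowSums((fit - observed)^2))))
}

# default 4-marker clusters for the unconstrained (6-DOF) comparator:
# three tracking markers plus the distal-lateral joint marker per segment;
# the foot uses the 4 shoe markers (toe composed at neutral MTP).
segment_cluster <- function(model, segment) {
  s <- model$segments[[segment]]
  if (s$name == "pelvis") {
    return(t(vapply(names(s$markers), function(l) s$markers[[l]], numeric(3))))
  }
  S <- toupper(s$side)
  if (grepl("^foot", s$name)) {
    toes <- model$segments[[paste0("toes_", tolower(S))]]
    mk <- s$markers
    mk[[paste0(S, ".Toe")]] <- toes$origin_in_parent + toes$markers[[paste0(S, ".Toe")]]
    return(t(vapply(names(mk), function(l) mk[[l]], numeric(3))))
  }
  t(vapply(names(s$markers), function(l) s$markers[[l]], numeric(3)))
}

#' Per-segment rigid-body pose series (unconstrained model)
#'
#' Fits each segment's pose independently per frame from its own 4-marker
#' cluster via [segment_pose_svd()]: the pelvis from its 4 markers, thigh
#' and shank from 3 tracking markers plus the distal-lateral joint marker,
#' and the foot from the 4 shoe markers.
#'
#' @param model a `constrained_model` (supplies local cluster geometry).
#' @param trial a gap-free `marker_trial`.
#' @param segments segment names to track.
#' @return List per segment with `R` (3 x 3 x frames), `t` (frames x 3),
#'   `rms` (per-frame fit residual).
#' @export
segment_pose_series <- function(model, trial,
                                segments = c("pelvis", "thigh_r", "shank_r",
                                             "foot_r", "thigh_l", "shank_l",
                                             "foot_l")) {
  nf <- n_frames(trial)
  out <- list()
  for (seg in segments) {
    local <- segment_cluster(model, seg)
    labs <- rownames(local)
    if (!all(labs %in% trial$labels))
      stop(sprintf("segment %s: missing markers %s", seg,
                   paste(setdiff(labs, trial$labels), collapse = ", ")))
    Rs <- array(NA_real_, c(3, 3, nf))
    ts <- matrix(NA_real_, nf, 3)
    rms <- numeric(nf)
    obs_all <- trial$coords[, , labs, drop = FALSE]
    for (f in seq_len(nf)) {
      fit <- segment_pose_svd(local, t(obs_all[f, , ]))
      Rs[, , f] <- fit$R
      ts[f, ] <- fit$t
      rms[f] <- fit$rms
    }
    out[[seg]] <- list(R = Rs, t = ts, rms = rms)
  }
  out
}

# joint angle decomposition used by the unconstrained comparator, with
# axes mirroring the constrained model's joint definitions
uncon_joint_angles_frame <- function(model, Rprox, Rdist, joint) {
  J <- model$joints[[joint]]
  Rj <- crossprod(Rprox, Rdist)   # t(Rprox) %*% Rdist
  if (J$type %in% c("ball", "mobile_hinge", "hinge")) {
    # floating flexion-adduction-rotation sequence on the joint's own axes
    sgn <- function(a, e) sum(a * e)  # axes are +-basis vectors
    ax <- J$axes
    if (J$type == "ball") {
      std <- decompose_zxy(Rj)
      c(flexion = std[[1]] * sgn(ax[, 1], c(0, 0, 1)),
        adduction = std[[2]] * sgn(ax[, 2], c(1, 0, 0)),
        rotation = std[[3]] * sgn(ax[, 3], c(0, 1, 0)))
    } else {
      std <- decompose_zxy(Rj)
      c(flexion = std[[1]] * sgn(ax[, 1], c(0, 0, 1)),
        adduction = std[[2]], rotation = std[[3]])
    }
  } else {
    th <- decompose_two_axis(Rj, J$axes[, 1], J$axes[, 2])
    c(flexion = th[1], adduction = NA_real_, rotation = th[2])
  }
}

#' Unconstrained joint kinematics with anatomic-pose offset matching
#'
#' Computes joint angles from independent per-segment rigid-body poses:
#' for each joint the relative rotation (proximal pose)^-1 (distal pose)
#' is decomposed with the floating flexion-adduction-rotation sequence
#' (hip, knee; flexion axis proximal, rotation axis distal, adduction
#' floating) or onto the model's oblique talocrural/subtalar axis pair
#' (ankle), mirroring the constrained model's joint definitions. Angles
#' are then offset so that at the anatomic (static) pose they equal the
#' constrained model's anatomic-pose angles, giving a one-to-one
#' comparison.
#'
#' @param model a (scaled) `constrained_model`.
#' @param trial a gap-free `marker_trial`.
#' @param static_markers the anatomic-pose marker frame (named list or
#'   matrix, as for [scale_model()]).
#' @param anatomic_angles named constrained-model joint angles at the
#'   anatomic pose (degrees); defaults to all zero (the neutral pose).
#' @return List with `angles` (frames x coordinates matrix, degrees,
#'   columns like `hip_flexion_r`), `offsets`, and `gimbal` (frames
#'   flagged within 1 degree of the adduction singularity).
#' @export
unconstrained_kinematics <- function(model, trial, static_markers,
                                     anatomic_angles = NULL) {
  poses <- segment_pose_series(model, trial)
  sm <- if (is.matrix(static_markers)) static_markers else do.call(rbind, static_markers)
  static_arr <- array(NA_real_, c(1, 3, nrow(sm)),
                      dimnames = list(NULL, c("x", "y", "z"), rownames(sm)))
  static_arr[1, , ] <- t(sm)
  static_poses <- segment_pose_series(model, marker_trial(static_arr, trial$rate))

  joints <- list(
    hip_r = c("pelvis", "thigh_r"), knee_r = c("thigh_r", "shank_r"),
    ankle_r = c("shank_r", "foot_r"),
    hip_l = c("pelvis", "thigh_l"), knee_l = c("thigh_l", "shank_l"),
    ankle_l = c("shank_l", "foot_l"))

  nf <- n_frames(trial)
  cols <- character(0)
  for (jn in names(joints)) {
    side <- sub(".*_", "", jn)
    base <- sub("_[rl]$", "", jn)
    cols <- c(cols, switch(base,
      hip = paste0(c("hip_flexion_", "hip_adduction_", "hip_rotation_"), side),
      knee = paste0(c("knee_flexion_", "knee_adduction_", "knee_rotation_"), side),
      ankle = paste0(c("ankle_dorsiflexion_", "subtalar_inversion_"), side)))
  }
  ang <- matrix(NA_real_, nf, length(cols), dimnames = list(NULL, cols))
  gimbal <- rep(FALSE, nf)

  if (is.null(anatomic_angles))
    anatomic_angles <- setNames(numeric(length(cols)), cols)

  offsets <- setNames(numeric(length(cols)), cols)
  for (jn in names(joints)) {
    pr <- joints[[jn]][1]; di <- joints[[jn]][2]
    side <- sub(".*_", "", jn)
    base <- sub("_[rl]$", "", jn)
    a_static <- uncon_joint_angles_frame(model, static_poses[[pr]]$R[, , 1],
                                         static_poses[[di]]$R[, , 1], jn)
    keep <- switch(base, hip = 1:3, knee = 1:3, ankle = c(1, 3))
    jcols <- switch(base,
      hip = paste0(c("hip_flexion_", "hip_adduction_", "hip_rotation_"), side),
      knee = paste0(c("knee_flexion_", "knee_adduction_", "knee_rotation_"), side),
      ankle = paste0(c("ankle_dorsiflexion_", "subtalar_inversion_"), side))
    ref <- anatomic_angles[jcols]
    ref[is.na(ref)] <- 0
    offsets[jcols] <- ref - a_static[keep]
    for (f in seq_len(nf)) {
      a <- uncon_joint_angles_frame(model, poses[[pr]]$R[, , f],
                                    poses[[di]]$R[, , f], jn)
      ang[f, jcols] <- a[keep] + offsets[jcols]
      if (base %in% c("hip", "knee") && abs(abs(a[2]) - 90) < 1) gimbal[f] <- TRUE
    }
  }
  list(angles = ang, offsets = offsets, gimbal = gimbal)
}
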