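# The constrained lower-extremity model: a kinematic tree rooted at the
# pelvis with a ball hip, a mobile-hinge knee (prescribed tibiofemoral
# translations driven by flexion), an oblique universal ankle complex
# (talocrural + subtalar) and a hinge forefoot. Positions mm, angles deg.

mirror_z <- function(v) c(v[1], v[2], -v[3])
mirror_axis <- function(a) c(-a[1], -a[2], a[3])

#' The eight thigh/shank tracking-marker labels
#'
#' The fixed universe of leg markers that the dropout sweep operates on, in
#' the canonical bitmask order Thigh1, Thigh2, Thigh3, LateralKnee, Shank1,
#' Shank2, Shank3, LateralAnkle. Trials carry side-prefixed labels
#' (`"R.Thigh1"`, `"L.LateralAnkle"`, ...).
#'
#' @return Character vector of length 8.
#' @export
leg_marker_universe <- function() {
  c("Thigh1", "Thigh2", "Thigh3", "LateralKnee",
    "Shank1", "Shank2", "Shank3", "LateralAnkle")
}

# Default knee prescribed-motion knot table: tibiofemoral translations in
# the tibial frame as functions of knee flexion, approximating published
# cadaver-based anterior-posterior rollback (up to ~18 mm) and
# superior-inferior shift (up to ~6 mm). Overridable via generic_model().
default_knee_knots <- function() {
  list(flexion = c(-15, 0, 30, 60, 90, 120, 135),
       ap = c(1.5, 0, -3, -8, -13, -17, -18.5),
       si = c(0.3, 0, 1.5, 3.5, 5, 6, 6.3))
}

# Default oblique ankle-complex axes (right side, shank/foot frames aligned
# at neutral): talocrural nearly mediolateral with slight posterior/inferior
# obliquity; subtalar pointing anterior-superior-medial. From the standard
# lower-limb model family; configurable.
default_ankle_axes <- function() {
  cbind(talocrural = unit3(c(-0.105, -0.174, 0.979)),
        subtalar = unit3(c(0.787, 0.605, -0.121)))
}

#' Build the generic lower-extremity model
#'
#' Constructs the unscaled bilateral lower-extremity chain: pelvis (6-DOF
#' root), thighs, shanks, feet and toe segments, with anatomic-landmark and
#' tracking markers placed from standard adult anthropometry. The hip is a
#' ball joint (flexion, adduction, internal rotation), the knee a
#' single-DOF mobile hinge whose tibiofemoral translations are prescribed
#' functions of flexion (non-sagittal knee rotations are locked), the ankle
#' an oblique universal joint (talocrural dorsiflexion + subtalar
#' inversion) and the forefoot a hinge. Total coordinate count is 20:
#' 6 pelvis + 7 per leg.
#'
#' @param hip_width_factor mediolateral widening applied to the generic hip
#'   joint centers when scaling with `widen_hips = TRUE` (dimensionless;
#'   default 1.3, i.e. functional hip centers 30% wider than the generic
#'   pelvis).
#' @param pure_hinge_knee if `TRUE` the knee's prescribed translations are
#'   identically zero (a plain hinge); useful for exact-limit comparisons.
#' @param knee_knots optional replacement knot table, a list with numeric
#'   `flexion`, `ap`, `si` (degrees, mm, mm).
#' @param ankle_axes optional 3x2 matrix of unit talocrural/subtalar axes
#'   (right side; the left side is mirrored automatically).
#' @return An object of class `constrained_model`.
#' @export
#' @examples
#' m <- generic_model()
#' length(coord_names(m))  # 20
generic_model <- function(hip_width_factor = 1.3, pure_hinge_knee = FALSE,
                          knee_knots = NULL, ankle_axes = NULL) {
  if (is.null(knee_knots)) knee_knots <- default_knee_knots()
  if (is.null(ankle_axes)) ankle_axes <- default_ankle_axes()
  stopifnot(hip_width_factor > 0)
  if (max(abs(sqrt(colSums(ankle_axes^2)) - 1)) > 1e-9)
    stop("ankle axes must be unit vectors")

  hip_r <- c(0, -70, 90)
  pelvis_markers <- list(
    R.ASIS = c(85, 10, 115), L.ASIS = mirror_z(c(85, 10, 115)),
    R.PSIS = c(-125, 35, 45), L.PSIS = mirror_z(c(-125, 35, 45)))
  thigh_markers_r <- list(
    R.Thigh1 = c(10, -140, 75),    # proximal-lateral
    R.Thigh2 = c(5, -300, 70),     # distal-lateral
    R.Thigh3 = c(65, -220, 15),    # middle-anterior
    R.LateralKnee = c(0, -400, 60))
  shank_markers_r <- list(
    R.Shank1 = c(15, -110, 55),
    R.Shank2 = c(5, -280, 52),
    R.Shank3 = c(42, -190, 8),
    R.LateralAnkle = c(-5, -390, 42))
  foot_markers_r <- list(
    R.Heel = c(-55, -55, 5), R.MT1 = c(120, -60, -30), R.MT5 = c(95, -60, 45))
  toes_markers_r <- list(R.Toe = c(55, -10, -10))

  knee_center <- c(0, -410, 0)
  ankle_center <- c(0, -400, 0)
  mtp_center <- c(130, -65, 0)

  side_markers <- function(mk, side) {
    out <- lapply(mk, if (side == "L") mirror_z else identity)
    names(out) <- sub("^R", side, names(out))
    out
  }

  segments <- list(
    pelvis = list(name = "pelvis", side = NA, parent = NA, parent_joint = NA,
                  origin_in_parent = c(0, 0, 0), markers = pelvis_markers,
                  scale_factors = c(1, 1, 1)))
  joints <- list()

  for (side in c("r", "l")) {
    S <- toupper(side)
    mz <- if (side == "l") mirror_z else identity
    ma <- if (side == "l") mirror_axis else identity
    segments[[paste0("thigh_", side)]] <- list(
      name = paste0("thigh_", side), side = S, parent = "pelvis",
      parent_joint = paste0("hip_", side), origin_in_parent = mz(hip_r),
      markers = side_markers(thigh_markers_r, S), scale_factors = c(1, 1, 1))
    segments[[paste0("shank_", side)]] <- list(
      name = paste0("shank_", side), side = S, parent = paste0("thigh_", side),
      parent_joint = paste0("knee_", side), origin_in_parent = mz(knee_center),
      markers = side_markers(shank_markers_r, S), scale_factors = c(1, 1, 1))
    segments[[paste0("foot_", side)]] <- list(
      name = paste0("foot_", side), side = S, parent = paste0("shank_", side),
      parent_joint = paste0("ankle_", side), origin_in_parent = mz(ankle_center),
      markers = side_markers(foot_markers_r, S), scale_factors = c(1, 1, 1))
    segments[[paste0("toes_", side)]] <- list(
      name = paste0("toes_", side), side = S, parent = paste0("foot_", side),
      parent_joint = paste0("mtp_", side), origin_in_parent = mz(mtp_center),
      markers = side_markers(toes_markers_r, S), scale_factors = c(1, 1, 1))

    joints[[paste0("hip_", side)]] <- list(
      name = paste0("hip_", side), type = "ball", parent = "pelvis",
      child = paste0("thigh_", side),
      axes = cbind(ma(c(0, 0, 1)), ma(c(1, 0, 0)), ma(c(0, 1, 0))),
      coords = paste0(c("hip_flexion_", "hip_adduction_", "hip_rotation_"), side),
      bounds = rbind(c(-45, 120), c(-45, 45), c(-60, 60)),
      prescribed = NULL)
    joints[[paste0("knee_", side)]] <- list(
      name = paste0("knee_", side), type = "mobile_hinge",
      parent = paste0("thigh_", side), child = paste0("shank_", side),
      axes = cbind(ma(c(0, 0, -1))),
      coords = paste0("knee_flexion_", side),
      bounds = rbind(c(-10, 130)),
      prescribed = if (pure_hinge_knee) NULL else list(
        flexion = knee_knots$flexion,
        ap = nat_spline_prep(knee_knots$flexion, knee_knots$ap),
        si = nat_spline_prep(knee_knots$flexion, knee_knots$si)))
    joints[[paste0("ankle_", side)]] <- list(
      name = paste0("ankle_", side), type = "universal",
      parent = paste0("shank_", side), child = paste0("foot_", side),
      axes = cbind(ma(ankle_axes[, 1]), ma(ankle_axes[, 2])),
      coords = paste0(c("ankle_dorsiflexion_", "subtalar_inversion_"), side),
      bounds = rbind(c(-60, 50), c(-35, 35)),
      prescribed = NULL)
    joints[[paste0("mtp_", side)]] <- list(
      name = paste0("mtp_", side), type = "hinge",
      parent = paste0("foot_", side), child = paste0("toes_", side),
      axes = cbind(ma(c(0, 0, 1))),
      coords = paste0("mtp_flexion_", side),
      bounds = rbind(c(-40, 70)),
      prescribed = NULL)
  }

  model <- structure(list(
    segments = segments, joints = joints,
    hip_width_factor = hip_width_factor,
    pure_hinge_knee = pure_hinge_knee,
    knee_knots = knee_knots,
    scaled = FALSE), class = "constrained_model")
  validate_model(model)
  model
}

validate_model <- function(model) {
  labs <- unlist(lapply(model$segments, function(s) names(s$markers)))
  if (anyDuplicated(labs)) stop("marker labels must be unique across segments")
  for (s in model$segments)
    if (any(s$scale_factors <= 0)) stop("scale factors must be strictly positive")
  nax <- c(ball = 3, mobile_hinge = 1, universal = 2, hinge = 1)
  for (j in model$joints) {
    if (ncol(j$axes) != nax[[j$type]])
      stop(sprintf("joint %s: %s joints take %d coordinate(s)", j$name, j$type, nax[[j$type]]))
    if (max(abs(sqrt(colSums(j$axes^2)) - 1)) > 1e-9)
      stop(sprintf("joint %s: axes must have unit norm", j$name))
    if (!is.null(j$prescribed) && j$type != "mobile_hinge")
      stop("prescribed motion is only valid for mobile_hinge joints")
  }
  # connected acyclic tree rooted at the pelvis
  for (s in model$segments)
    if (s$name != "pelvis" && !s$parent %in% names(model$segments))
      stop(sprintf("segment %s has unknown parent", s$name))
  invisible(model)
}

#' Generalized-coordinate names of a model
#'
#' The 20 coordinates, in solver order: pelvis translations (`pelvis_tx`,
#' `pelvis_ty`, `pelvis_tz`, mm), pelvis orientation (`pelvis_tilt`,
#' `pelvis_list`, `pelvis_rotation`, degrees, Z-X-Y mobile sequence), then
#' per leg (right, left) hip flexion/adduction/rotation, knee flexion,
#' ankle dorsiflexion, subtalar inversion and toe (MTP) flexion.
#'
#' @param model a `constrained_model`.
#' @return Character vector of length 20.
#' @export
coord_names <- function(model) {
  c("pelvis_tx", "pelvis_ty", "pelvis_tz",
    "pelvis_tilt", "pelvis_list", "pelvis_rotation",
    unlist(lapply(c("r", "l"), function(side)
      unlist(lapply(paste0(c("hip_", "knee_", "ankle_", "mtp_"), side), function(jn)
        model$joints[[jn]]$coords), use.names = FALSE)), use.names = FALSE))
}

#' Coordinate bounds of a model
#'
#' @param model a `constrained_model`.
#' @return A 20x2 matrix (lower, upper); mm for pelvis translations,
#'   degrees elsewhere. Pelvis translations are effectively unbounded.
#' @export
coord_bounds <- function(model) {
  b <- rbind(matrix(rep(c(-1e6, 1e6), each = 3), 3, 2),
             matrix(rep(c(-180, 180), each = 3), 3, 2))
  for (side in c("r", "l"))
    for (jn in paste0(c("hip_", "knee_", "ankle_", "mtp_"), side))
      b <- rbind(b, model$joints[[jn]]$bounds)
  rownames(b) <- coord_names(model)
  colnames(b) <- c("lower", "upper")
  b
}

#' Neutral pose of a model
#'
#' @param model a `constrained_model`.
#' @return Named numeric vector of length 20, all zeros (pelvis at the lab
#'   origin, all joint angles zero).
#' @export
neutral_pose <- function(model) {
  setNames(numeric(20), coord_names(model))
}

#' All marker labels of a model
#' @param model a `constrained_model`.
#' @return Character vector in canonical order (pelvis, then right and left
#'   thigh, shank, foot, toes).
#' @export
model_markers <- function(model) {
  unlist(lapply(model$segments, function(s) names(s$markers)), use.names = FALSE)
}

# segment that owns each marker label
marker_segment_map <- function(model) {
  out <- character(0)
  for (s in model$segments)
    out[names(s$markers)] <- s$name
  out
}

#' Prescribed tibiofemoral motion of the mobile-hinge knee
#'
#' Evaluates the knee's prescribed translations (tibial frame) at the given
#' flexion angles via the model's natural-cubic-spline knot table. The
#' non-sagittal knee rotations are locked at zero by construction; for a
#' pure-hinge model the translations are identically zero. At zero flexion
#' the reference alignment `(0, 0)` is returned.
#'
#' @param flexion numeric vector of knee flexion angles (degrees).
#' @param model a `constrained_model` (supplies the knot table).
#' @return A data.frame with columns `ap` (anterior translation, mm), `si`
#'   (superior translation, mm), `valgus` and `internal_rotation` (always
#'   0, degrees).
#' @export
knee_prescribed_motion <- function(flexion, model = generic_model()) {
  j <- model$joints$knee_r
  if (any(flexion < j$bounds[1, 1] | flexion > j$bounds[1, 2]))
    stop("flexion outside knee bounds")
  if (is.null(j$prescribed)) {
    ap <- si <- numeric(length(flexion))
  } else {
    ap <- nat_spline_eval(j$prescribed$ap, flexion)
    si <- nat_spline_eval(j$prescribed$si, flexion)
  }
  data.frame(flexion = flexion, ap = ap, si = si,
             valgus = 0, internal_rotation = 0)
}
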