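# The marker-dropout sweep: every subset of the eight thigh/shank tracking
# markers (2^8 = 256 combinations, applied to both legs simultaneously) is
# re-solved with constrained IK and scored against the full-marker
# reference from the same trial.

#' Enumerate all thigh/shank marker combinations
#'
#' All 256 subsets of the eight-marker universe (see
#' [leg_marker_universe()]), ordered by cardinality and then
#' lexicographically by included-marker position. The inclusion bitmask is
#' an 8-character string ordered Thigh1, Thigh2, Thigh3, LateralKnee,
#' Shank1, Shank2, Shank3, LateralAnkle.
#'
#' @return A list of `marker_combination` objects, each with `included`
#'   (labels), `mask`, `cardinality` and flags `is_full`, `is_empty`,
#'   `is_simplified` (the pelvis + lateral knee + lateral malleolus +
#'   shoes set).
#' @export
#' @examples
#' length(marker_combinations())  # 256
marker_combinations <- function() {
  universe <- leg_marker_universe()
  out <- list()
  for (k in 0:8) {
    sets <- if (k == 0) list(integer(0)) else
      asplit(utils::combn(8, k), 2)
    for (idx in sets) {
      idx <- as.integer(idx)
      mask <- paste(ifelse(seq_len(8) %in% idx, "1", "0"), collapse = "")
      out[[length(out) + 1]] <- structure(list(
        included = universe[idx], mask = mask, cardinality = k,
        is_full = k == 8, is_empty = k == 0,
        is_simplified = identical(sort(universe[idx]),
                                  sort(c("LateralKnee", "LateralAnkle")))),
        class = "marker_combination")
    }
  }
  out
}

#' Build a combination from its bitmask
#' @param mask 8-character string of 0/1, ordered Thigh1..LateralAnkle.
#' @return A `marker_combination`.
#' @export
combination_from_mask <- function(mask) {
  stopifnot(grepl("^[01]{8}$", mask))
  all <- marker_combinations()
  all[[which(vapply(all, function(cc) cc$mask, "") == mask)]]
}

# trial marker labels for a combination: pelvis + shoes always, plus the
# included leg markers on both sides
combination_trial_markers <- function(model, combo) {
  always <- c("R.ASIS", "L.ASIS", "R.PSIS", "L.PSIS",
              "R.Heel", "R.MT1", "R.MT5", "R.Toe",
              "L.Heel", "L.MT1", "L.MT5", "L.Toe")
  if (!length(combo$included)) return(always)
  c(always, paste0("R.", combo$included), paste0("L.", combo$included))
}

# the coordinates scored by the sweep (both sides)
sweep_coordinates <- function() {
  c("hip_flexion", "hip_adduction", "hip_rotation", "knee_flexion",
    "ankle_dorsiflexion")
}

# stride-averaged gait curves of the scored coordinates, per side
ik_angle_curves <- function(ik, strides_by_side) {
  out <- list()
  for (side in c("r", "l")) {
    st <- strides_by_side[[toupper(side)]]
    cols <- paste0(sweep_coordinates(), "_", side)
    out[[side]] <- time_normalize(ik$q[, cols], st)
  }
  out
}

# stride-averaged joint-center trajectories (3 axes per center), per side
ik_center_curves <- function(ik, strides_by_side) {
  out <- list()
  for (side in c("r", "l")) {
    st <- strides_by_side[[toupper(side)]]
    cen <- paste0(c("hip_", "knee_", "ankle_"), side)
    x <- aperm(ik$joint_centers[, cen, , drop = FALSE], c(3, 1, 2))
    dim(x) <- c(dim(x)[1], 9)  # columns: (x,y,z) for hip, knee, ankle
    out[[side]] <- time_normalize(x, st)
  }
  out
}

#' Joint-center error between two normalized center trajectories
#'
#' Per-axis (anterior-posterior X, superior-inferior Y, medial-lateral Z,
#' lab frame) and overall RMS of the displacement between joint-center
#' trajectories from a reduced marker set and from the complete-set
#' reference, over the normalized gait cycle.
#'
#' @param centers,centers_ref `n x 3` matrices (or length-3n vectors) of a
#'   center's trajectory on a common cycle grid (mm).
#' @return Named numeric: `ap`, `si`, `ml`, `overall` RMS (mm).
#' @export
joint_center_error <- function(centers, centers_ref) {
  a <- as.matrix(centers); b <- as.matrix(centers_ref)
  if (!all(dim(a) == dim(b))) stop("alignment error: grids differ")
  d <- a - b
  c(ap = sqrt(mean(d[, 1]^2)), si = sqrt(mean(d[, 2]^2)),
    ml = sqrt(mean(d[, 3]^2)), overall = sqrt(mean(rowSums(d^2))))
}

#' Run the marker-dropout sweep
#'
#' For each marker combination, re-runs constrained IK with only that
#' subset of thigh/shank markers (pelvis and shoe markers always
#' included), stride-averages the joint-angle and joint-center
#' trajectories, and scores them against the full-marker reference from
#' the same trial. Both legs share the subset; per-coordinate metrics are
#' pooled (averaged) over legs.
#'
#' @param model a scaled `constrained_model`.
#' @param trial a conditioned (gap-free, filtered) `marker_trial`.
#' @param combinations list of `marker_combination`s (default: all 256).
#' @param strides optional list with `R` and `L` `stride_index` objects;
#'   detected from the trial if omitted.
#' @param speed_label optional label copied into the records.
#' @param verbose print progress every 32 combinations.
#' @return List with `angles` (data.frame: mask, cardinality, coordinate,
#'   rms_deg, r_xy, rom_delta_deg, peak_max_delta_deg, peak_min_delta_deg,
#'   failed), `centers` (data.frame: mask, cardinality, center, rms_ap_mm,
#'   rms_si_mm, rms_ml_mm, rms_overall_mm, failed), and `reference` (the
#'   full-set curves).
#' @export
run_sweep <- function(model, trial, combinations = marker_combinations(),
                      strides = NULL, speed_label = NA, verbose = FALSE) {
  if (is.null(strides))
    strides <- list(R = detect_heel_strikes(trial, "R"),
                    L = detect_heel_strikes(trial, "L"))

  ref_ik <- constrained_ik(model, trial)
  if (any(!ref_ik$converged))
    stop(sprintf("reference IK failed to converge on %d frame(s)",
                 sum(!ref_ik$converged)))
  ref_ang <- ik_angle_curves(ref_ik, strides)
  ref_cen <- ik_center_curves(ref_ik, strides)

  coords <- sweep_coordinates()
  ang_rows <- list()
  cen_rows <- list()
  for (ci in seq_along(combinations)) {
    combo <- combinations[[ci]]
    if (verbose && ci %% 32 == 0)
      message(sprintf("sweep: %d/%d combinations", ci, length(combinations)))
    rec <- tryCatch({
      ik <- constrained_ik(model, trial,
                           included_markers = combination_trial_markers(model, combo))
      ang <- ik_angle_curves(ik, strides)
      cen <- ik_center_curves(ik, strides)
      a_rows <- lapply(seq_along(coords), function(j) {
        per_side <- vapply(c("r", "l"), function(sd) {
          x <- ang[[sd]]$values[, j]; y <- ref_ang[[sd]]$values[, j]
          rp <- rom_and_peaks(x); rr <- rom_and_peaks(y)
          c(rms_error(x, y), cross_correlation(x, y),
            rp[["range"]] - rr[["range"]], rp[["max"]] - rr[["max"]],
            rp[["min"]] - rr[["min"]])
        }, numeric(5))
        m <- rowMeans(per_side)
        data.frame(mask = combo$mask, cardinality = combo$cardinality,
                   coordinate = coords[j], rms_deg = m[1], r_xy = m[2],
                   rom_delta_deg = m[3], peak_max_delta_deg = m[4],
                   peak_min_delta_deg = m[5], speed = speed_label,
                   failed = FALSE)
      })
      c_rows <- lapply(c("hip", "knee", "ankle"), function(cn) {
        k <- match(cn, c("hip", "knee", "ankle"))
        colsel <- (k - 1) * 3 + 1:3
        per_side <- vapply(c("r", "l"), function(sd) {
          joint_center_error(cen[[sd]]$values[, colsel],
                             ref_cen[[sd]]$values[, colsel])
        }, numeric(4))
        m <- rowMeans(per_side)
        data.frame(mask = combo$mask, cardinality = combo$cardinality,
                   center = cn, rms_ap_mm = m[1], rms_si_mm = m[2],
                   rms_ml_mm = m[3], rms_overall_mm = m[4],
                   speed = speed_label, failed = FALSE)
      })
      list(a = do.call(rbind, a_rows), c = do.call(rbind, c_rows))
    }, error = function(e) {
      list(a = data.frame(mask = combo$mask, cardinality = combo$cardinality,
                          coordinate = NA, rms_deg = NA, r_xy = NA,
                          rom_delta_deg = NA, peak_max_delta_deg = NA,
                          peak_min_delta_deg = NA, speed = speed_label,
                          failed = TRUE),
           c = data.frame(mask = combo$mask, cardinality = combo$cardinality,
                          center = NA, rms_ap_mm = NA, rms_si_mm = NA,
                          rms_ml_mm = NA, rms_overall_mm = NA,
                          speed = speed_label, failed = TRUE))
    })
    ang_rows[[ci]] <- rec$a
    cen_rows[[ci]] <- rec$c
  }
  list(angles = do.call(rbind, ang_rows),
       centers = do.call(rbind, cen_rows),
       reference = list(angles = ref_ang, centers = ref_cen))
}
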