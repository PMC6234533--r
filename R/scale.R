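# Model scaling from a static neutral-pose capture. Landmark pairs follow
# gait-lab practice: pelvis from the inter-ASIS distance; thigh from ASIS
# to lateral knee condyle; shank from lateral condyle to lateral malleolus;
# foot (and toes) from lateral malleolus to the toe marker. Because three
# of the pairs span a joint, each distal factor is solved from the chain
# (a scalar quadratic) rather than read off as a raw distance ratio, so a
# model regenerated from its own static pose returns factors of exactly 1.

static_marker_pos <- function(static_markers, label) {
  if (is.matrix(static_markers)) {
    if (!label %in% rownames(static_markers))
      stop(sprintf("missing landmark marker: %s", label))
    return(as.numeric(static_markers[label, ]))
  }
  if (!label %in% names(static_markers))
    stop(sprintf("missing landmark marker: %s", label))
  as.numeric(static_markers[[label]])
}

static_dist <- function(static_markers, a, b) {
  sqrt(sum((static_marker_pos(static_markers, a) -
              static_marker_pos(static_markers, b))^2))
}

# solve s from | d - s * c | = m, preferring the positive root nearest ref
solve_chain_factor <- function(d, c_local, m, ref, what) {
  cc <- sum(c_local^2)
  if (cc < 1e-9) stop(sprintf("degenerate generic geometry for %s", what))
  disc <- sum(d * c_local)^2 - cc * (sum(d^2) - m^2)
  if (disc < 0)
    stop(sprintf("static landmark distances inconsistent with the model (%s)", what))
  r <- (sum(d * c_local) + c(-1, 1) * sqrt(disc)) / cc
  r <- r[r > 0]
  if (!length(r))
    stop(sprintf("no positive scale factor for %s", what))
  r[which.min(abs(r - ref))]
}

#' Scale a generic model to a subject from a static pose
#'
#' Scales each segment of the generic model so that the anatomic-landmark
#' distances measured in a static neutral-pose capture are reproduced:
#' pelvis from the inter-ASIS distance, thigh from ASIS-to-lateral-condyle,
#' shank from condyle-to-malleolus, and foot/toes from malleolus-to-toe.
#' Each segment is scaled isotropically; local marker positions and distal
#' joint-center locations scale with their segment. With
#' `widen_hips = TRUE` the mediolateral hip-center offsets of the generic
#' model are first multiplied by `model$hip_width_factor` (default 1.3,
#' reflecting functional hip centers ~30% wider than the generic pelvis).
#'
#' @param model a (generic) `constrained_model`; it is not modified.
#' @param static_markers single-frame marker map: a named list of length-3
#'   vectors or a matrix with marker-label rownames (mm). Must contain the
#'   ASIS/PSIS, lateral condyle, lateral malleolus, heel, MT1, MT5 and toe
#'   markers for both sides.
#' @param widen_hips apply the hip-width factor before scaling.
#' @return A new `constrained_model` with `scaled = TRUE` and per-segment
#'   `scale_factors` recorded.
#' @export
scale_model <- function(model, static_markers, widen_hips = TRUE) {
  stopifnot(inherits(model, "constrained_model"))
  landmarks <- c("R.ASIS", "L.ASIS", "R.PSIS", "L.PSIS",
                 "R.LateralKnee", "L.LateralKnee",
                 "R.LateralAnkle", "L.LateralAnkle",
                 "R.Heel", "L.Heel", "R.MT1", "L.MT1",
                 "R.MT5", "L.MT5", "R.Toe", "L.Toe")
  for (lab in landmarks) static_marker_pos(static_markers, lab)

  out <- model
  if (widen_hips) {
    for (side in c("r", "l")) {
      seg <- paste0("thigh_", side)
      out$segments[[seg]]$origin_in_parent[3] <-
        out$segments[[seg]]$origin_in_parent[3] * model$hip_width_factor
    }
  }

  seg <- out$segments
  g_asis <- sqrt(sum((seg$pelvis$markers$R.ASIS - seg$pelvis$markers$L.ASIS)^2))
  if (g_asis < 1e-6) stop("degenerate generic inter-ASIS distance")
  s_pelvis <- static_dist(static_markers, "R.ASIS", "L.ASIS") / g_asis

  factors <- list(pelvis = s_pelvis)
  for (side in c("r", "l")) {
    S <- toupper(side)
    thigh <- seg[[paste0("thigh_", side)]]
    shank <- seg[[paste0("shank_", side)]]
    foot <- seg[[paste0("foot_", side)]]
    toes <- seg[[paste0("toes_", side)]]

    # thigh: ASIS (pelvis) to lateral condyle (thigh)
    d <- s_pelvis * (seg$pelvis$markers[[paste0(S, ".ASIS")]] - thigh$origin_in_parent)
    cl <- thigh$markers[[paste0(S, ".LateralKnee")]]
    m <- static_dist(static_markers, paste0(S, ".ASIS"), paste0(S, ".LateralKnee"))
    s_thigh <- solve_chain_factor(d, cl, m, m / sqrt(sum((d / s_pelvis - cl)^2)),
                                  paste0("thigh_", side))

    # shank: lateral condyle (thigh) to lateral malleolus (shank)
    d <- s_thigh * (thigh$markers[[paste0(S, ".LateralKnee")]] - shank$origin_in_parent)
    cl <- shank$markers[[paste0(S, ".LateralAnkle")]]
    m <- static_dist(static_markers, paste0(S, ".LateralKnee"), paste0(S, ".LateralAnkle"))
    s_shank <- solve_chain_factor(d, cl, m, s_thigh, paste0("shank_", side))

    # foot/toes: lateral malleolus (shank) to toe (toes)
    d <- s_shank * (shank$markers[[paste0(S, ".LateralAnkle")]] - foot$origin_in_parent)
    cl <- toes$origin_in_parent + toes$markers[[paste0(S, ".Toe")]]
    m <- static_dist(static_markers, paste0(S, ".LateralAnkle"), paste0(S, ".Toe"))
    s_foot <- solve_chain_factor(d, cl, m, s_shank, paste0("foot_", side))

    factors[[paste0("thigh_", side)]] <- s_thigh
    factors[[paste0("shank_", side)]] <- s_shank
    factors[[paste0("foot_", side)]] <- s_foot
    factors[[paste0("toes_", side)]] <- s_foot
  }

  out <- apply_scale_factors(out, factors)
  out$scaled <- TRUE
  out
}

# Multiply each segment's local geometry by an isotropic factor; a child's
# origin_in_parent scales with the *parent* segment.
apply_scale_factors <- function(model, factors) {
  out <- model
  for (nm in names(out$segments)) {
    s <- out$segments[[nm]]
    f <- factors[[nm]]
    if (is.null(f)) f <- 1
    if (any(f <= 0)) stop("scale factors must be strictly positive")
    s$markers <- lapply(s$markers, function(p) p * f)
    s$scale_factors <- s$scale_factors * f
    if (!is.na(s$parent)) {
      fp <- factors[[s$parent]]
      if (is.null(fp)) fp <- 1
      s$origin_in_parent <- s$origin_in_parent * fp
    }
    out$segments[[nm]] <- s
  }
  out
}

#' Per-segment scale factors of a model
#' @param model a `constrained_model`.
#' @return Named numeric vector (mean per-axis factor per segment).
#' @export
scale_factors <- function(model) {
  vapply(model$segments, function(s) mean(s$scale_factors), numeric(1))
}
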