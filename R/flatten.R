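# Flatten a constrained_model into plain arrays for the compiled forward
# kinematics / IK solver. Column-major layout; all indices 0-based.

model_flat <- function(model) {
  segs <- model$segments
  nseg <- length(segs)
  seg_idx <- setNames(seq_along(segs) - 1L, names(segs))
  cn <- coord_names(model)
  qpos <- setNames(seq_along(cn) - 1L, cn)

  parent <- integer(nseg)
  origin <- matrix(0, 3, nseg)
  naxes <- integer(nseg)
  axes <- matrix(0, 3, 3 * nseg)
  qidx <- matrix(-1L, 3, nseg)
  presc <- integer(nseg)

  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (s$name == "pelvis") {
      parent[i] <- -1L
      naxes[i] <- 3L
      axes[, (3 * (i - 1) + 1):(3 * i)] <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
      qidx[, i] <- c(qpos[["pelvis_tilt"]], qpos[["pelvis_list"]],
                     qpos[["pelvis_rotation"]])
    } else {
      parent[i] <- seg_idx[[s$parent]]
      origin[, i] <- s$origin_in_parent
      j <- model$joints[[s$parent_joint]]
      k <- ncol(j$axes)
      naxes[i] <- k
      axes[, (3 * (i - 1) + 1):(3 * (i - 1) + k)] <- j$axes
      qidx[seq_len(k), i] <- qpos[j$coords]
      presc[i] <- as.integer(!is.null(j$prescribed))
    }
  }

  labels <- model_markers(model)
  segmap <- marker_segment_map(model)
  marker_seg <- vapply(labels, function(l) seg_idx[[segmap[[l]]]], integer(1))
  marker_local <- vapply(labels, function(l) {
    segs[[segmap[[l]]]]$markers[[l]]
  }, numeric(3))

  pres <- model$joints$knee_r$prescribed
  spline <- if (is.null(pres)) {
    list(x = c(0, 1), ap_y = c(0, 0), ap_ypp = c(0, 0),
         si_y = c(0, 0), si_ypp = c(0, 0))
  } else {
    list(x = pres$ap$x, ap_y = pres$ap$y, ap_ypp = pres$ap$ypp,
         si_y = pres$si$y, si_ypp = pres$si$ypp)
  }

  list(nseg = nseg, nq = length(cn), nmark = length(labels),
       parent = as.integer(parent), origin = origin,
       naxes = as.integer(naxes), axes = axes,
       qidx = matrix(as.integer(qidx), 3, nseg),
       presc = as.integer(presc), spline = spline,
       marker_seg = as.integer(marker_seg), marker_local = marker_local,
       labels = labels, bounds = unname(coord_bounds(model)),
       coord_names = cn)
}
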