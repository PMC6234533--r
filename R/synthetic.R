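# Synthetic treadmill-gait generator: ground-truth poses from a Fourier
# gait template with speed-calibrated ranges of motion, forward kinematics
# to marker trajectories, a calibrated segment-frame soft-tissue-artifact
# model, measurement noise and optional gaps. Every trial carries its
# exact truth (poses and heel-strike events), so each pipeline stage can
# be tested by parameter recovery.

#' Reference soft-tissue-artifact magnitudes by walking speed
#'
#' Per-marker RMS artifact targets (mm) for the eight thigh/shank markers
#' at each belt speed, used to calibrate the artifact generator.
#'
#' @param speed `"slow"` (0.9 m/s), `"moderate"` (1.2 m/s) or `"fast"`
#'   (1.5 m/s).
#' @return Named numeric vector over [leg_marker_universe()].
#' @export
sta_reference_targets <- function(speed = c("slow", "moderate", "fast")) {
  speed <- match.arg(speed)
  tab <- rbind(
    slow = c(13.0, 9.0, 12.3, 13.0, 9.5, 5.4, 6.1, 5.0),
    moderate = c(13.5, 10.4, 11.8, 13.6, 9.6, 5.5, 6.7, 5.2),
    fast = c(14.2, 10.4, 13.7, 15.7, 9.2, 5.7, 7.1, 5.7))
  setNames(tab[speed, ], leg_marker_universe())
}

#' Gait-curve template for the synthetic generator
#'
#' Per-coordinate Fourier-series shapes over the gait cycle together with
#' speed-dependent range-of-motion targets. Each joint curve is
#' `offset + scale * sum_j amp_j cos(2 pi k_j (phase - phase_j))`, with
#' `scale` chosen so the range of motion equals the target for the belt
#' speed (linear interpolation between the three calibrated speeds).
#' Sagittal hip/knee/ankle and hip adduction/rotation ranges grow with
#' speed; pelvis channels are fixed-amplitude oscillations. The returned
#' list can be edited before being passed to [generate_trial()].
#'
#' @return A `gait_template` list with elements `coords` (per-coordinate
#'   harmonics, offset, ROM targets, `speed_sensitive` flag), `pelvis`
#'   and `stride_time_coef` (stride period = a + b * speed).
#' @export
gait_template <- function() {
  h <- function(k, amp, phase) data.frame(k = k, amp = amp, phase = phase)
  rom <- function(s, m, f) c(`0.9` = s, `1.2` = m, `1.5` = f)
  structure(list(
    coords = list(
      hip_flexion = list(harmonics = h(c(1, 2), c(1, 0.10), c(0.97, 0.45)),
                         offset = 8, rom_by_speed = rom(38.8, 42.7, 47.2),
                         speed_sensitive = TRUE),
      hip_adduction = list(harmonics = h(c(1, 2), c(1, 0.3), c(0.08, 0.30)),
                           offset = 2, rom_by_speed = rom(17.0, 18.8, 20.4),
                           speed_sensitive = TRUE),
      hip_rotation = list(harmonics = h(1, 1, 0.30),
                          offset = 1, rom_by_speed = rom(10.0, 12.3, 13.8),
                          speed_sensitive = TRUE),
      knee_flexion = list(harmonics = h(c(1, 2), c(1, 0.48), c(0.73, 0.735)),
                          offset = 26, rom_by_speed = rom(63.1, 65.6, 65.6),
                          speed_sensitive = FALSE),
      ankle_dorsiflexion = list(harmonics = h(c(1, 2, 3), c(0.5, 1, 0.35),
                                              c(0.45, 0.52, 0.58)),
                                offset = 2, rom_by_speed = rom(22.4, 26.1, 29.2),
                                speed_sensitive = TRUE),
      subtalar_inversion = list(harmonics = h(c(1, 2), c(1, 0.4), c(0.10, 0.60)),
                                offset = 0, rom_by_speed = rom(8, 8, 8),
                                speed_sensitive = FALSE),
      mtp_flexion = list(harmonics = h(c(1, 2), c(1, 0.45), c(0.60, 0.62)),
                         offset = 8, rom_by_speed = rom(25, 25, 25),
                         speed_sensitive = FALSE)),
    pelvis = list(
      pelvis_tx = list(harmonics = h(c(1, 2), c(5, 8), c(0.30, 0.05)), offset = 0),
      pelvis_ty = list(harmonics = h(2, 12, 0.30), offset = 5),
      pelvis_tz = list(harmonics = h(1, 12, 0.30), offset = 0),
      pelvis_tilt = list(harmonics = h(2, 1.5, 0.10), offset = 3),
      pelvis_list = list(harmonics = h(1, 2, 0.15), offset = 0),
      pelvis_rotation = list(harmonics = h(1, 4, 0.95), offset = 0)),
    stride_time_coef = c(1.35, -0.2)), class = "gait_template")
}

# raw Fourier shape (zero mean over the cycle)
template_shape <- function(harmonics, phase) {
  out <- numeric(length(phase))
  for (i in seq_len(nrow(harmonics)))
    out <- out + harmonics$amp[i] *
      cos(2 * pi * harmonics$k[i] * (phase - harmonics$phase[i]))
  out
}

template_rom_target <- function(spec, speed) {
  sp <- as.numeric(names(spec$rom_by_speed))
  approx(sp, spec$rom_by_speed, xout = speed, rule = 2)$y
}

# joint-coordinate value over the cycle, ROM-calibrated for the speed
template_coord <- function(spec, phase, speed, rom_mult = 1, offset_shift = 0) {
  grid <- seq(0, 1, length.out = 201)
  raw <- template_shape(spec$harmonics, grid)
  scale <- rom_mult * template_rom_target(spec, speed) / (max(raw) - min(raw))
  spec$offset + offset_shift + scale * template_shape(spec$harmonics, phase)
}

#' Stride period for a belt speed
#' @param template a `gait_template`.
#' @param speed belt speed (m/s).
#' @return Stride time in seconds.
#' @export
stride_time <- function(template, speed) {
  template$stride_time_coef[1] + template$stride_time_coef[2] * speed
}

#' Soft-tissue-artifact model
#'
#' Configures the per-marker artifact generator: a gait-phase-locked
#' component (random-direction harmonics in the segment frame, moving with
#' the limb as skin does) mixed with a slow AR(1) random walk, scaled so
#' the realized 3-D RMS over the trial equals the per-marker target
#' exactly.
#'
#' @param targets named RMS targets (mm) over [leg_marker_universe()]
#'   (applied to both sides) and/or full trial labels; markers not listed
#'   get zero artifact.
#' @param support_targets artifact on the always-included markers: pelvis
#'   (ASIS/PSIS) and shoe markers. Skin-mounted pelvis markers and shoes
#'   are not artifact-free in real captures even though dropout sweeps
#'   never remove them; defaults are literature-scale (6 mm pelvis, 4 mm
#'   shoe). Set to `NULL` for rigid support markers.
#' @param phase_frac fraction of artifact power in the phase-locked
#'   component (default 0.7).
#' @param segment_coherence fraction of artifact power shared by all
#'   markers on one segment (default 0.8). Skin and the underlying soft
#'   tissue deform and wobble as a smooth field, so most artifact energy
#'   is a near-rigid cluster motion common to a segment's markers rather
#'   than independent per-marker noise.
#' @param ar1 AR(1) coefficient of the random-walk component at 100 Hz
#'   (default 0.985, a drift time constant of roughly 0.7 s, so the
#'   artifact survives 6 Hz low-pass filtering largely intact).
#' @return An `artifact_model` list.
#' @export
artifact_model <- function(targets = sta_reference_targets("slow"),
                           support_targets = c(ASIS = 6, PSIS = 6, Heel = 4,
                                               MT1 = 4, MT5 = 4, Toe = 4),
                           phase_frac = 0.7, segment_coherence = 0.8,
                           ar1 = 0.985) {
  stopifnot(phase_frac >= 0, phase_frac <= 1, ar1 >= 0, ar1 < 1,
            segment_coherence >= 0, segment_coherence <= 1)
  structure(list(targets = c(targets, support_targets),
                 phase_frac = phase_frac,
                 segment_coherence = segment_coherence, ar1 = ar1),
            class = "artifact_model")
}

rms3 <- function(m) sqrt(mean(rowSums(m^2)))

# a unit-scaled phase-locked displacement pattern (2 random harmonics)
phase_locked_pattern <- function(phase) {
  pl <- matrix(0, length(phase), 3)
  for (comp in 1:2) {
    k <- sample(1:2, 1)
    dirn <- rnorm(3); dirn <- dirn / sqrt(sum(dirn^2))
    ph <- runif(1)
    pl <- pl + outer(cos(2 * pi * k * (phase - ph)), dirn)
  }
  pl / rms3(pl)
}

# a unit-scaled AR(1) drift series
ar1_pattern <- function(ar1, nf) {
  ar <- matrix(0, nf, 3)
  sd0 <- 1 / sqrt(1 - ar1^2)
  for (d in 1:3) {
    x <- numeric(nf)
    x[1] <- rnorm(1, 0, sd0)
    eta <- rnorm(nf - 1)
    for (t in 2:nf) x[t] <- ar1 * x[t - 1] + eta[t - 1]
    ar[, d] <- x
  }
  ar / rms3(ar)
}

# One marker's artifact displacement (nf x 3, segment frame), split into
# a segment-common part (one near-rigid cluster motion per segment, its
# amplitude set by the segment's smallest marker target so no marker is
# dominated by its neighbours) and a marker-specific remainder that tops
# the total 3-D RMS up to the marker's target. Both parts mix a
# phase-locked pattern with an AR(1) drift.
realize_artifact <- function(art, target, phase, nf, shared = NULL,
                             common_amp = 0) {
  if (target <= 0) return(NULL)
  mix <- function(pl, ar) sqrt(art$phase_frac) * pl +
    sqrt(1 - art$phase_frac) * ar
  own <- mix(phase_locked_pattern(phase), ar1_pattern(art$ar1, nf))
  c_amp <- if (is.null(shared)) 0 else min(common_amp, 0.95 * target)
  common <- if (c_amp > 0) c_amp * mix(shared$pl, shared$ar) else 0 * own
  own_amp <- sqrt(max(target^2 - c_amp^2, (0.05 * target)^2))
  list(common = common, own = own_amp * own)
}

#' Generate a synthetic subject
#'
#' Samples anthropometric scale factors around the generic model (pelvis,
#' thigh, shank, foot; bilaterally symmetric), builds the subject's scaled
#' model, computes the static neutral-pose marker frame by forward
#' kinematics, and samples subject-level curve variability (per-coordinate
#' ROM multiplier, baseline offset and phase jitter).
#'
#' @param seed RNG seed.
#' @param generic the generic model to perturb.
#' @param anthro_sd s.d. of the scale factors (default 0.05).
#' @param rom_sd s.d. of the per-coordinate ROM multiplier (default 0.06).
#' @param offset_sd s.d. of per-coordinate baseline shifts, degrees
#'   (default 2).
#' @param phase_sd s.d. of the subject's curve phase jitter, cycle
#'   fraction (default 0.01).
#' @return A `synthetic_subject`: list with `model`, `static` (marker
#'   matrix), `factors`, `rom_mult`, `offset_shift`, `phase_shift`,
#'   `seed`.
#' @export
generate_subject <- function(seed, generic = generic_model(),
                             anthro_sd = 0.05, rom_sd = 0.06,
                             offset_sd = 2, phase_sd = 0.01) {
  set.seed(seed)
  f4 <- pmax(rnorm(4, 1, anthro_sd), 0.7)
  factors <- list(pelvis = f4[1],
                  thigh_r = f4[2], thigh_l = f4[2],
                  shank_r = f4[3], shank_l = f4[3],
                  foot_r = f4[4], foot_l = f4[4],
                  toes_r = f4[4], toes_l = f4[4])
  model <- apply_scale_factors(generic, factors)
  model$scaled <- TRUE
  static <- neutral_markers(model)
  cn <- names(gait_template()$coords)
  structure(list(model = model, static = static,
                 factors = unlist(factors),
                 rom_mult = setNames(pmax(rnorm(length(cn), 1, rom_sd), 0.5), cn),
                 offset_shift = setNames(rnorm(length(cn), 0, offset_sd), cn),
                 phase_shift = rnorm(1, 0, phase_sd),
                 seed = seed), class = "synthetic_subject")
}

# gait phase at the peak of heel anterior displacement relative to the
# pelvis origin -- the generator's definition of a heel-strike event
template_event_phase <- function(subject, speed, template) {
  grid <- seq(0, 1, length.out = 401)[-401]
  q <- truth_pose_matrix(subject, template, speed, grid, grid + 0.5)
  flat <- model_flat(subject$model)
  fk <- fk_batch_cpp(flat, q)
  labs <- flat$labels
  hx <- fk$markers[1, match("R.Heel", labs), ] -
    (fk$markers[1, match("R.PSIS", labs), ] + fk$markers[1, match("L.PSIS", labs), ]) / 2
  grid[which.max(hx)]
}

# pose matrix from per-frame right/left leg phases
truth_pose_matrix <- function(subject, template, speed, phase_r, phase_l) {
  nf <- length(phase_r)
  q <- matrix(0, nf, 20)
  colnames(q) <- coord_names(subject$model)
  for (nm in names(template$pelvis)) {
    spec <- template$pelvis[[nm]]
    q[, nm] <- spec$offset + template_shape(spec$harmonics, phase_r)
  }
  for (nm in names(template$coords)) {
    spec <- template$coords[[nm]]
    q[, paste0(nm, "_r")] <- template_coord(spec, phase_r, speed,
                                            subject$rom_mult[[nm]],
                                            subject$offset_shift[[nm]])
    q[, paste0(nm, "_l")] <- template_coord(spec, phase_l, speed,
                                            subject$rom_mult[[nm]],
                                            subject$offset_shift[[nm]])
  }
  q
}

#' Generate a synthetic treadmill walking trial
#'
#' Builds ground-truth poses from the gait template (cadence-consistent
#' phase with stride-to-stride period jitter), runs forward kinematics,
#' then adds segment-frame soft-tissue artifact, isotropic measurement
#' noise and (optionally) marker gaps. Heel-strike truth events are the
#' frames at which the noise-free heel anterior displacement relative to
#' the pelvis peaks.
#'
#' @param subject a `synthetic_subject`.
#' @param speed belt speed (m/s; the study speeds are 0.9, 1.2, 1.5).
#' @param duration_s trial length in seconds (default 120, approximately
#'   100 strides per leg).
#' @param artifact an [artifact_model()], or `NULL` for rigid markers.
#' @param noise_sd isotropic Gaussian measurement noise s.d. (mm;
#'   default 0.3).
#' @param rate capture frame rate (Hz, default 100).
#' @param seed RNG seed.
#' @param template a [gait_template()].
#' @param stride_jitter_sd stride-to-stride period jitter, fractional
#'   (default 0.02).
#' @param gaps optional list `list(n, max_len)`: inject `n` random
#'   interior gaps of up to `max_len` frames across markers.
#' @param calibrate `"proxy"` (default) calibrates each marker's injected
#'   artifact so that the full-pipeline soft-tissue-artifact proxy (IK
#'   residual RMS on the filtered trial, see [sta_proxy()]) reproduces the
#'   target -- the quantity the reference magnitudes actually are; the IK
#'   fit absorbs a marker-dependent share of the injected displacement, so
#'   injection is scaled up by that factor (measured on a calibration
#'   window with one IK pass). `"injected"` calibrates the raw injected
#'   displacement RMS to the target instead.
#' @return List with `trial` (a `marker_trial`), `truth` (list: `q` pose
#'   matrix, `events` with per-side heel-strike frames, `phase_r`,
#'   `phase_l`, `stride_times`, `event_phase`) and `subject`.
#' @export
generate_trial <- function(subject, speed, duration_s = 120,
                           artifact = artifact_model(), noise_sd = 0.3,
                           rate = 100, seed = 1,
                           template = gait_template(),
                           stride_jitter_sd = 0.02, gaps = NULL,
                           calibrate = c("proxy", "injected")) {
  calibrate <- match.arg(calibrate)
  stopifnot(inherits(subject, "synthetic_subject"))
  T0 <- stride_time(template, speed)
  if (duration_s < 2 * T0) stop("trial shorter than two strides")
  set.seed(seed)

  # stride boundaries with period jitter, then piecewise-linear phase
  t_ends <- 0
  while (tail(t_ends, 1) < duration_s + 2 * T0)
    t_ends <- c(t_ends, tail(t_ends, 1) + T0 * (1 + rnorm(1, 0, stride_jitter_sd)))
  tt <- seq(0, duration_s, by = 1 / rate)
  nf <- length(tt)
  stride_of <- findInterval(tt, t_ends)
  phase_r <- (stride_of - 1 + (tt - t_ends[stride_of]) /
                (t_ends[stride_of + 1] - t_ends[stride_of])) + subject$phase_shift
  phase_l <- phase_r + 0.5

  q <- truth_pose_matrix(subject, template, speed, phase_r, phase_l)
  flat <- model_flat(subject$model)
  fk <- fk_batch_cpp(flat, q)
  labs <- flat$labels
  coords <- aperm(fk$markers, c(3, 1, 2))  # nf x 3 x nmark
  dimnames(coords) <- list(NULL, c("x", "y", "z"), labs)

  # segment-frame artifact, applied before the world transform
  noise <- if (noise_sd > 0)
    array(rnorm(length(coords), 0, noise_sd), dim(coords)) else 0
  if (!is.null(artifact)) {
    segmap <- marker_segment_map(subject$model)
    seg_index <- setNames(seq_along(subject$model$segments),
                          names(subject$model$segments))
    # one coherent displacement field per segment, marker-specific remainder
    shared <- lapply(names(subject$model$segments), function(sn) {
      ph <- if (endsWith(sn, "_l")) phase_l else phase_r
      list(pl = phase_locked_pattern(ph), ar = ar1_pattern(artifact$ar1, nf))
    })
    names(shared) <- names(subject$model$segments)
    marker_target <- function(lab) {
      target <- artifact$targets[lab]
      if (is.na(target)) target <- artifact$targets[sub("^[RL]\\.", "", lab)]
      if (is.na(target)) 0 else unname(target)
    }
    targets <- vapply(labs, marker_target, numeric(1))
    # per-segment common amplitude: scaled to the smallest target on the
    # segment so every marker keeps a free marker-specific remainder
    common_amp <- vapply(names(subject$model$segments), function(sn) {
      t_seg <- targets[segmap[labs] == sn & targets > 0]
      if (!length(t_seg)) 0 else sqrt(artifact$segment_coherence) * min(t_seg)
    }, numeric(1))
    Dlist <- vector("list", length(labs))
    for (j in seq_along(labs)) {
      if (targets[j] <= 0) next
      lab <- labs[j]
      side_phase <- if (startsWith(lab, "L.")) phase_l else phase_r
      Dlist[[j]] <- realize_artifact(artifact, targets[j], side_phase, nf,
                                     shared = shared[[segmap[[lab]]]],
                                     common_amp = common_amp[[segmap[[lab]]]])
      if (calibrate == "injected") {
        tot <- Dlist[[j]]$common + Dlist[[j]]$own
        sc <- targets[j] / rms3(tot)
        Dlist[[j]]$common <- Dlist[[j]]$common * sc
        Dlist[[j]]$own <- Dlist[[j]]$own * sc
      }
    }
    apply_artifact <- function(base, Dlist) {
      out <- base
      for (j in seq_along(labs)) {
        if (is.null(Dlist[[j]])) next
        D <- Dlist[[j]]$common + Dlist[[j]]$own
        s <- seg_index[[segmap[[labs[j]]]]]
        Rc <- fk$seg_R[, (3 * (s - 1) + 1):(3 * s), , drop = FALSE]
        for (d in 1:3)
          out[, d, j] <- out[, d, j] + Rc[d, 1, ] * D[, 1] +
            Rc[d, 2, ] * D[, 2] + Rc[d, 3, ] * D[, 3]
      }
      out
    }
    if (calibrate == "proxy") {
      # IK passes on a calibration window measure how much of each
      # marker's injected displacement the chain fit absorbs; the
      # marker-specific remainder is rescaled by the inverse so the
      # pipeline-level proxy matches the target. The common part stays
      # fixed (rescaling it would shift every marker on the segment), and
      # the update is damped because absorption couples markers.
      win <- seq_len(min(nf, 1500))
      for (pass in 1:4) {
        cal <- apply_artifact(coords, Dlist) + noise
        cal_trial <- marker_trial(cal[win, , , drop = FALSE], rate)
        cal_ik <- constrained_ik(subject$model, lowpass_filter(cal_trial))
        pr <- sta_proxy(cal_ik)
        ratios <- rep(NA_real_, length(labs))
        for (j in seq_along(labs)) {
          if (is.null(Dlist[[j]])) next
          ratios[j] <- pr[[labs[j]]] / targets[j]
        }
        if (max(abs(ratios - 1), na.rm = TRUE) < 0.04) break
        for (j in seq_along(labs))
          if (is.finite(ratios[j]) && ratios[j] > 0.2)
            Dlist[[j]]$own <- Dlist[[j]]$own / ratios[j]^0.7
      }
    }
    coords <- apply_artifact(coords, Dlist)
  }
  coords <- coords + noise

  if (!is.null(gaps)) {
    for (g in seq_len(gaps$n)) {
      j <- sample(length(labs), 1)
      len <- sample(gaps$max_len, 1)
      at <- sample(seq(2, nf - len - 1), 1)
      coords[at:(at + len - 1), , j] <- NA
    }
  }

  trial <- marker_trial(coords, rate,
                        meta = list(speed = speed, subject = subject$seed,
                                    duration_s = duration_s))

  # truth events: phase crossings of the heel-forward peak phase
  ev_phase <- template_event_phase(subject, speed, template)
  event_frames <- function(phase) {
    ks <- seq(ceiling(min(phase) - 1), floor(max(phase)) + 1)
    out <- integer(0)
    for (k in ks + ev_phase) {
      i <- which(phase[-nf] <= k & phase[-1] > k)
      if (length(i) == 1) {
        frac <- (k - phase[i]) / (phase[i + 1] - phase[i])
        out <- c(out, i + as.integer(round(frac)))
      }
    }
    sort(out[out >= 1 & out <= nf])
  }
  truth <- list(q = q, events = list(R = event_frames(phase_r),
                                     L = event_frames(phase_l)),
                phase_r = phase_r, phase_l = phase_l,
                stride_times = diff(t_ends), event_phase = ev_phase)
  list(trial = trial, truth = truth, subject = subject)
}

#' Generate a synthetic study cohort on disk
#'
#' Writes TRC trial files, static-pose TRC files, per-trial ground-truth
#' CSVs and a JSON manifest for a cohort of synthetic subjects walking at
#' the study speeds, enabling the whole pipeline to run end-to-end from
#' files.
#'
#' @param dir output directory (created if needed).
#' @param n_subjects cohort size (default 10).
#' @param speeds belt speeds (default `c(0.9, 1.2, 1.5)` m/s).
#' @param seed master seed; per-subject and per-trial seeds are derived
#'   from it deterministically.
#' @param duration_s trial length (s).
#' @param artifact an [artifact_model()] or `NULL`.
#' @param noise_sd measurement noise (mm).
#' @param rate frame rate (Hz).
#' @return The manifest (invisibly also written to `manifest.json`):
#'   list with per-trial subject id, speed, seed and file paths.
#' @export
generate_cohort <- function(dir, n_subjects = 10, speeds = c(0.9, 1.2, 1.5),
                            seed = 1, duration_s = 120,
                            artifact = artifact_model(), noise_sd = 0.3,
                            rate = 100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  subj_seeds <- sample.int(1e7, n_subjects)
  trial_seeds <- matrix(sample.int(1e7, n_subjects * length(speeds)),
                        n_subjects, length(speeds))
  trials <- list()
  for (i in seq_len(n_subjects)) {
    subj <- generate_subject(subj_seeds[i])
    static_path <- file.path(dir, sprintf("subject%02d_static.trc", i))
    static_arr <- array(NA_real_, c(1, 3, nrow(subj$static)),
                        dimnames = list(NULL, c("x", "y", "z"),
                                        rownames(subj$static)))
    static_arr[1, , ] <- t(subj$static)
    write_trc(marker_trial(static_arr, rate), static_path)
    for (k in seq_along(speeds)) {
      gt <- generate_trial(subj, speeds[k], duration_s = duration_s,
                           artifact = artifact, noise_sd = noise_sd,
                           rate = rate, seed = trial_seeds[i, k])
      trc_path <- file.path(dir, sprintf("subject%02d_speed%0.1f.trc", i, speeds[k]))
      truth_path <- file.path(dir, sprintf("subject%02d_speed%0.1f_truth.csv", i, speeds[k]))
      write_trc(gt$trial, trc_path)
      truth_df <- data.frame(frame = seq_len(nrow(gt$truth$q)), gt$truth$q,
                             check.names = FALSE)
      truth_df$heel_strike_r <- truth_df$frame %in% gt$truth$events$R
      truth_df$heel_strike_l <- truth_df$frame %in% gt$truth$events$L
      write.table(truth_df, truth_path, sep = ",", row.names = FALSE, quote = FALSE)
      trials[[length(trials) + 1]] <- list(
        subject = i, subject_seed = subj_seeds[i], speed = speeds[k],
        trial_seed = trial_seeds[i, k], trc = trc_path, truth = truth_path,
        static = static_path)
    }
  }
  manifest <- list(n_subjects = n_subjects, speeds = speeds, seed = seed,
                   duration_s = duration_s, rate = rate, trials = trials)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
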