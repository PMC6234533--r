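# The constrained model: construction, scaling, forward kinematics and
# the knee's prescribed tibiofemoral motion.

test_that("the generic model has the expected structure", {
  m <- generic_model()
  expect_length(coord_names(m), 20)
  expect_length(model_markers(m), 28)
  # every marker belongs to exactly one segment
  expect_false(anyDuplicated(model_markers(m)) > 0)
  # joint coordinate counts by type
  types <- vapply(m$joints, `[[`, "", "type")
  nax <- vapply(m$joints, function(j) ncol(j$axes), integer(1))
  expect_equal(unname(nax[types == "ball"]), rep(3L, 2))
  expect_equal(unname(nax[types == "universal"]), rep(2L, 2))
  expect_equal(unname(nax[types %in% c("hinge", "mobile_hinge")]), rep(1L, 4))
  for (j in m$joints)
    expect_equal(sqrt(colSums(j$axes^2)), rep(1, ncol(j$axes)), tolerance = 1e-12)
})

test_that("scaling recovers identity, similarity and hip widening", {
  m <- generic_model()
  st <- forward_kinematics(m, neutral_pose(m))$markers
  s1 <- scale_model(m, st, widen_hips = FALSE)
  expect_equal(unname(scale_factors(s1)), rep(1, 9), tolerance = 1e-12)
  s2 <- scale_model(m, st * 2, widen_hips = FALSE)
  expect_equal(unname(scale_factors(s2)), rep(2, 9), tolerance = 1e-12)
  # widened hips: inter-hip distance = widening factor x ML pelvis scale
  sw <- scale_model(m, st, widen_hips = TRUE)
  jc0 <- forward_kinematics(m, neutral_pose(m))$joint_centers
  jcw <- forward_kinematics(sw, neutral_pose(sw))$joint_centers
  d0 <- sqrt(sum((jc0["hip_r", ] - jc0["hip_l", ])^2))
  dw <- sqrt(sum((jcw["hip_r", ] - jcw["hip_l", ])^2))
  expect_equal(dw / d0, m$hip_width_factor, tolerance = 1e-12)
})

test_that("scaling a model from its own static pose returns factors 1", {
  subj <- generate_subject(21)
  again <- scale_model(subj$model, neutral_markers(subj$model),
                       widen_hips = FALSE)
  ratio <- scale_factors(again) / scale_factors(subj$model)
  expect_equal(unname(ratio), rep(1, 9), tolerance = 1e-9)
})

test_that("mirrored static poses give equal left/right scale factors", {
  subj <- generate_subject(13)
  st <- subj$static
  f <- scale_factors(scale_model(generic_model(), st, widen_hips = FALSE))
  for (seg in c("thigh", "shank", "foot"))
    expect_equal(f[[paste0(seg, "_r")]], f[[paste0(seg, "_l")]],
                 tolerance = 1e-9)
})

test_that("scaling errors on missing landmarks and degenerate geometry", {
  m <- generic_model()
  st <- neutral_markers(m)
  expect_error(scale_model(m, st[rownames(st) != "R.ASIS", ]),
               "missing landmark marker: R.ASIS")
  bad <- m
  bad$segments$pelvis$markers$R.ASIS <- bad$segments$pelvis$markers$L.ASIS
  expect_error(scale_model(bad, st), "degenerate")
})

test_that("forward kinematics: neutral pose, translation equivariance, bounds", {
  m <- generic_model()
  q <- neutral_pose(m)
  fk <- forward_kinematics(m, q)
  # neutral: markers at composed local positions; pelvis markers literal
  expect_equal(fk$markers["R.ASIS", ],
               c(x = 85, y = 10, z = 115), tolerance = 1e-12)
  # within-segment distances equal local distances
  th <- m$segments$thigh_r$markers
  expect_equal(sqrt(sum((fk$markers["R.Thigh1", ] - fk$markers["R.LateralKnee", ])^2)),
               sqrt(sum((th$R.Thigh1 - th$R.LateralKnee)^2)), tolerance = 1e-9)
  q2 <- q
  q2[c("pelvis_tx", "pelvis_ty", "pelvis_tz")] <- c(10, 0, 0)
  fk2 <- forward_kinematics(m, q2)
  expect_equal(fk2$markers, fk$markers + rep(c(10, 0, 0), each = 28),
               tolerance = 1e-12)
  expect_equal(fk2$joint_centers, fk$joint_centers + rep(c(10, 0, 0), each = 8),
               tolerance = 1e-12)
  qb <- q
  qb["knee_flexion_r"] <- 200
  expect_error(forward_kinematics(m, qb), "knee_flexion_r")
})

test_that("knee flexion matches a hand-composed single-chain transform", {
  m <- generic_model()
  q <- neutral_pose(m)
  q["knee_flexion_r"] <- 60
  fk <- forward_kinematics(m, q)
  # independent composition: shank frame = knee center + rotation about
  # the knee axis by 60 deg plus the prescribed translation (tibia frame)
  R <- rot_about(c(0, 0, -1), 60)
  pm <- knee_prescribed_motion(60, m)
  knee_w <- c(0, -70 - 410, 90)
  shank_origin <- knee_w + as.vector(R %*% c(pm$ap, pm$si, 0))
  for (lab in names(m$segments$shank_r$markers)) {
    expected <- shank_origin + as.vector(R %*% m$segments$shank_r$markers[[lab]])
    expect_equal(unname(fk$markers[lab, ]), expected, tolerance = 1e-9)
  }
  # foot rides along rigidly
  expected_ankle <- shank_origin + as.vector(R %*% c(0, -400, 0))
  expect_equal(unname(fk$joint_centers["ankle_r", ]), expected_ankle,
               tolerance = 1e-9)
})

test_that("within-segment isometry holds at random poses", {
  m <- generic_model()
  b <- coord_bounds(m)
  set.seed(2)
  for (rep in 1:5) {
    q <- neutral_pose(m)
    q[7:20] <- runif(14, pmax(b[7:20, 1], -30), pmin(b[7:20, 2], 60))
    fk <- forward_kinematics(m, q)
    for (seg in c("thigh_r", "shank_l", "foot_r")) {
      mk <- m$segments[[seg]]$markers
      labs <- names(mk)
      for (i in 1:(length(labs) - 1)) {
        dl <- sqrt(sum((mk[[labs[i]]] - mk[[labs[i + 1]]])^2))
        dw <- sqrt(sum((fk$markers[labs[i], ] - fk$markers[labs[i + 1], ])^2))
        expect_equal(dw, dl, tolerance = 1e-9)
      }
    }
  }
})

test_that("forward kinematics is continuous in q", {
  m <- generic_model()
  set.seed(3)
  q <- neutral_pose(m)
  q[7:20] <- runif(14, -5, 20)
  fk0 <- forward_kinematics(m, q)$markers
  eps <- 1e-3
  for (k in c("hip_flexion_r", "knee_flexion_l", "ankle_dorsiflexion_r")) {
    qp <- q
    qp[k] <- qp[k] + eps
    d <- max(abs(forward_kinematics(m, qp)$markers - fk0))
    # bounded by (max lever arm ~1 m) * eps in radians, with slack
    expect_lt(d, 30 * eps)
  }
})

test_that("knee prescribed motion: reference alignment, locked rotations, spline oracle", {
  m <- generic_model()
  pm0 <- knee_prescribed_motion(0, m)
  expect_equal(c(pm0$ap, pm0$si), c(0, 0), tolerance = 1e-12)
  fl <- seq(-10, 125, by = 5)
  pm <- knee_prescribed_motion(fl, m)
  expect_true(all(pm$valgus == 0 & pm$internal_rotation == 0))
  # natural-spline oracle at knot midpoints
  kk <- default_knee_knots()
  ap_oracle <- splinefun(kk$flexion, kk$ap, method = "natural")
  si_oracle <- splinefun(kk$flexion, kk$si, method = "natural")
  mid <- head(kk$flexion, -1) + diff(kk$flexion) / 2
  mid <- mid[mid >= -10 & mid <= 130]
  pmm <- knee_prescribed_motion(mid, m)
  expect_equal(pmm$ap, ap_oracle(mid), tolerance = 1e-9)
  expect_equal(pmm$si, si_oracle(mid), tolerance = 1e-9)
  expect_error(knee_prescribed_motion(135, m), "bounds")
  # pure hinge: identically zero
  ph <- generic_model(pure_hinge_knee = TRUE)
  expect_equal(knee_prescribed_motion(60, ph)$ap, 0)
})

test_that("model YAML serialization round-trips", {
  subj <- generate_subject(3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(subj$model, path)
  back <- read_model_yaml(path)
  q <- neutral_pose(back)
  set.seed(4)
  q[7:20] <- runif(14, -5, 25)
  fk1 <- forward_kinematics(subj$model, q)
  fk2 <- forward_kinematics(back, q)
  expect_equal(fk2$markers, fk1$markers, tolerance = 1e-9)
  expect_equal(back$knee_knots, subj$model$knee_knots)
})
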