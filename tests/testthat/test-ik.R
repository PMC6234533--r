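# Constrained IK, the soft-tissue-artifact proxy, SVD rigid pose fits and
# the unconstrained comparator.

test_that("constrained IK recovers exact-model poses (full and simplified sets)", {
  fx <- fixture_rigid()
  gt <- fx$gt
  angle_cols <- 7:20
  ik <- constrained_ik(fx$subject$model, gt$trial)
  expect_true(all(ik$converged))
  expect_lt(max(abs(ik$q[, angle_cols] - gt$truth$q[, angle_cols])), 0.1)
  expect_lt(max(ik$residuals, na.rm = TRUE), 1e-6)
  # joint centers within 0.5 mm of truth
  flat <- kinsweep:::model_flat(fx$subject$model)
  fk_true <- kinsweep:::fk_batch_cpp(flat, gt$truth$q)
  expect_lt(max(abs(ik$joint_centers - fk_true$seg_t[, -1, ])), 0.5)

  simp <- combination_from_mask("00010001")
  iks <- constrained_ik(fx$subject$model, gt$trial,
                        included_markers = kinsweep:::combination_trial_markers(
                          fx$subject$model, simp))
  expect_lt(max(abs(iks$q[, angle_cols] - gt$truth$q[, angle_cols])), 0.1)
})

test_that("IK residual RMS matches injected artifact magnitude in order", {
  fx <- fixture_artifact()
  ik <- constrained_ik(fx$subject$model, fx$filtered)
  pr <- sta_proxy(ik)
  tgt <- sta_reference_targets("slow")
  for (u in names(tgt)) {
    got <- mean(pr[paste0(c("R.", "L."), u)])
    expect_gt(got, 0.5 * tgt[[u]])
    expect_lt(got, 1.5 * tgt[[u]])
  }
  # thigh markers carry roughly twice the shank artifact, as configured
  thigh <- mean(pr[c("R.Thigh1", "R.Thigh2", "R.Thigh3",
                     "L.Thigh1", "L.Thigh2", "L.Thigh3")])
  shank <- mean(pr[c("R.Shank1", "R.Shank2", "R.Shank3",
                     "L.Shank1", "L.Shank2", "L.Shank3")])
  expect_gt(thigh / shank, 1.3)
})

test_that("sta_proxy is near zero on rigid data and localized to the injected marker", {
  fx <- fixture_rigid()
  ik <- constrained_ik(fx$subject$model, fx$gt$trial)
  expect_lt(max(sta_proxy(ik)), 1e-6)

  # artifact on Thigh1 only
  subj <- fx$subject
  art <- artifact_model(targets = c(Thigh1 = 13), support_targets = NULL)
  gt <- generate_trial(subj, 0.9, duration_s = 20, artifact = art,
                       noise_sd = 0, seed = 6)
  ik1 <- constrained_ik(subj$model, lowpass_filter(gt$trial))
  pr <- sta_proxy(ik1)
  expect_equal(unname(pr["R.Thigh1"]), 13, tolerance = 0.15 * 13)
  others <- pr[setdiff(names(pr), c("R.Thigh1", "L.Thigh1"))]
  expect_lt(max(others), 4)
})

test_that("doubling injected artifact roughly doubles the proxy", {
  subj <- generate_subject(17)
  base <- c(Thigh1 = 4, Shank2 = 2)
  pr <- lapply(c(1, 2), function(mult) {
    gt <- generate_trial(subj, 0.9, duration_s = 20,
                         artifact = artifact_model(targets = base * mult,
                                                   support_targets = NULL),
                         noise_sd = 0, seed = 9, calibrate = "injected")
    sta_proxy(constrained_ik(subj$model, lowpass_filter(gt$trial)))
  })
  ratio <- pr[[2]][c("R.Thigh1", "L.Thigh1", "R.Shank2", "L.Shank2")] /
    pr[[1]][c("R.Thigh1", "L.Thigh1", "R.Shank2", "L.Shank2")]
  expect_true(all(abs(ratio - 2) < 0.3))
})

test_that("segment_pose_svd: identity, exact rotation, reflection safety, degeneracy", {
  local <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 80, 0), c(20, 30, 60))
  fit <- segment_pose_svd(local, local)
  expect_equal(fit$R, diag(3), tolerance = 1e-12)
  expect_equal(fit$t, c(0, 0, 0), tolerance = 1e-12)

  set.seed(8)
  for (i in 1:10) {
    ax <- rnorm(3)
    R0 <- rot_about(ax, runif(1, -170, 170))
    t0 <- rnorm(3, 0, 500)
    obs <- sweep(local %*% t(R0), 2, t0, "+")
    fit <- segment_pose_svd(local, obs)
    expect_lt(max(abs(fit$R - R0)), 1e-9)
    expect_lt(max(abs(fit$t - t0)), 1e-9)
    expect_equal(det(fit$R), 1, tolerance = 1e-9)
  }
  line <- cbind(seq_len(4) * 10, 0, 0)
  expect_error(segment_pose_svd(line, line), "collinear")
})

test_that("segment_pose_svd matches a brute-force nonlinear least-squares fit", {
  local <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 80, 0), c(20, 30, 60))
  set.seed(12)
  pose_cost <- function(p, obs) {
    R <- kinsweep:::euler_zxy(p[1:3])
    sum((sweep(local %*% t(R), 2, p[4:6], "+") - obs)^2)
  }
  for (i in 1:25) {
    R0 <- rot_about(rnorm(3), runif(1, -60, 60))
    t0 <- rnorm(3, 0, 100)
    obs <- sweep(local %*% t(R0), 2, t0, "+") + matrix(rnorm(12, 0, 1), 4)
    fit <- segment_pose_svd(local, obs)
    p0 <- c(decompose_zxy(fit$R), fit$t) + rnorm(6, 0, 0.1)
    opt <- optim(p0, pose_cost, obs = obs, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))
    cost_svd <- pose_cost(c(decompose_zxy(fit$R), fit$t), obs)
    # the SVD solution is at least as good as the iterative optimum
    expect_lte(cost_svd, opt$value + 1e-6)
  }
})

test_that("Euler sequences compose and decompose consistently", {
  expect_equal(as.numeric(decompose_zxy(euler_zxy(c(20, 10, 5)))), c(20, 10, 5),
               tolerance = 1e-9, ignore_attr = TRUE)
  # pure rotation about the flexion axis
  expect_equal(as.numeric(decompose_zxy(rot_about(c(0, 0, 1), 30))), c(30, 0, 0),
               tolerance = 1e-9, ignore_attr = TRUE)
  # two-axis (universal) decomposition round trip on oblique axes
  a1 <- kinsweep:::unit3(c(-0.105, -0.174, 0.979))
  a2 <- kinsweep:::unit3(c(0.787, 0.605, -0.121))
  set.seed(5)
  for (i in 1:10) {
    th <- runif(2, -40, 40)
    R <- rot_about(a1, th[1]) %*% rot_about(a2, th[2])
    expect_equal(kinsweep:::decompose_two_axis(R, a1, a2), th, tolerance = 1e-9)
  }
})

test_that("constrained and unconstrained kinematics agree in the exact limit", {
  fx <- fixture_pure_hinge()
  ik <- constrained_ik(fx$subject$model, fx$gt$trial)
  un <- unconstrained_kinematics(fx$subject$model, fx$gt$trial,
                                 fx$subject$static)
  for (cc in c("hip_flexion_r", "knee_flexion_r", "ankle_dorsiflexion_r",
               "hip_flexion_l", "knee_flexion_l", "ankle_dorsiflexion_l",
               "hip_adduction_r", "hip_rotation_r"))
    expect_rms(un$angles[, cc], ik$q[, cc], 0.1)
  # offset matching: distal pose == proximal-chain pose at the anatomic frame
  expect_lt(max(abs(un$offsets)), 1e-6)
})

test_that("joint angles are invariant to a global lab-frame rotation", {
  fx <- fixture_rigid()
  gt <- fx$gt
  Rlab <- rot_about(c(0, 1, 0), 37)
  tr2 <- gt$trial
  nf <- n_frames(tr2)
  for (j in seq_along(tr2$labels)) {
    tr2$coords[, , j] <- tr2$coords[, , j] %*% t(Rlab)
  }
  ik1 <- constrained_ik(fx$subject$model, gt$trial)
  ik2 <- constrained_ik(fx$subject$model, tr2)
  expect_lt(max(abs(ik1$q[, 7:20] - ik2$q[, 7:20])), 1e-6)
})

test_that("IK solutions do not depend on the warm-start path", {
  fx <- fixture_artifact()
  tr <- fx$filtered
  sub <- tr
  keep <- 1:800
  sub$coords <- tr$coords[keep, , , drop = FALSE]
  sub$gap <- tr$gap[keep, , drop = FALSE]
  rev_t <- sub
  rev_t$coords <- sub$coords[rev(keep), , , drop = FALSE]
  ik_f <- constrained_ik(fx$subject$model, sub)
  ik_r <- constrained_ik(fx$subject$model, rev_t)
  d <- ik_f$q[, 7:20] - ik_r$q[rev(keep), 7:20]
  expect_lt(sqrt(mean(d^2)), 0.01)
})

test_that("downsampling the trial changes normalized curves only marginally", {
  fx <- fixture_artifact()
  tr <- fx$filtered
  half <- tr
  half$coords <- tr$coords[seq(1, n_frames(tr), by = 2), , , drop = FALSE]
  half$gap <- tr$gap[seq(1, n_frames(tr), by = 2), , drop = FALSE]
  half$rate <- tr$rate / 2
  ik1 <- constrained_ik(fx$subject$model, tr)
  ik2 <- constrained_ik(fx$subject$model, half)
  st1 <- detect_heel_strikes(tr, "R")
  st2 <- (st1$strides + 1) / 2  # the same events on the halved grid
  c1 <- time_normalize(ik1$q[, "knee_flexion_r"], st1)
  c2 <- time_normalize(ik2$q[, "knee_flexion_r"], st2)
  expect_rms(curve_values(c1), curve_values(c2), 0.2)
})

test_that("IK validates marker sets and observability", {
  fx <- fixture_rigid()
  m <- fx$subject$model
  tr <- fx$gt$trial
  expect_error(constrained_ik(m, tr, included_markers = c("R.ASIS", "Bogus")),
               "not in the model")
  few <- setdiff(model_markers(m), c("L.PSIS", "R.PSIS"))
  expect_error(constrained_ik(m, tr, included_markers = few), "pelvis")
  legless <- c("R.ASIS", "L.ASIS", "R.PSIS", "L.PSIS",
               "R.Heel", "R.MT1", "R.MT5", "R.Toe")
  expect_error(constrained_ik(m, tr, included_markers = legless),
               "observability")
})
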