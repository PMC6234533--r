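# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# subject + 10 s rigid (no artifact, no noise) trial at 1.2 m/s
fixture_rigid <- function() {
  with_cache("rigid", {
    subj <- generate_subject(7)
    gt <- generate_trial(subj, 1.2, duration_s = 10, artifact = NULL,
                         noise_sd = 0, seed = 3)
    list(subject = subj, gt = gt)
  })
}

# pure-hinge knee, locked forefoot, no baseline offsets: the exact-limit
# fixture for constrained/unconstrained equivalence
fixture_pure_hinge <- function() {
  with_cache("pure_hinge", {
    subj <- generate_subject(5, generic = generic_model(pure_hinge_knee = TRUE),
                             offset_sd = 0)
    tpl <- gait_template()
    tpl$coords$mtp_flexion$rom_by_speed[] <- 1e-6
    tpl$coords$mtp_flexion$offset <- 0
    gt <- generate_trial(subj, 1.2, duration_s = 10, artifact = NULL,
                         noise_sd = 0, seed = 4, template = tpl)
    list(subject = subj, gt = gt)
  })
}

# 40 s slow-speed trial with reference-magnitude artifact, filtered
fixture_artifact <- function() {
  with_cache("artifact", {
    subj <- generate_subject(7)
    gt <- generate_trial(subj, 0.9, duration_s = 40,
                         artifact = artifact_model(), noise_sd = 0.3,
                         seed = 11)
    list(subject = subj, gt = gt, filtered = lowpass_filter(gt$trial))
  })
}

expect_rms <- function(x, y, tol) {
  testthat::expect_lt(sqrt(mean((x - y)^2)), tol)
}
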