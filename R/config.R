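# Run configuration: every open parameter of the pipeline in one
# serializable object, so a run is reproducible from (config, seed,
# inputs) alone.

#' Default run configuration
#'
#' Collects every tunable of the pipeline: filter settings, IK optimizer
#' controls, sweep policy, statistics thresholds (the 5-degree
#' equivalence threshold, the 0.90 cross-correlation cutoff, alpha) and
#' synthetic-cohort settings. Override fields via `...` (nested lists are
#' replaced wholesale).
#'
#' @param ... named overrides, e.g. `filter = list(cutoff_hz = 8, order = 2)`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    filter = list(cutoff_hz = 6, order = 4),
    gaps = list(max_gap = 10),
    events = list(min_sep_frac = 0.4, duration_band = c(0.6, 2.5)),
    ik = list(xtol = 1e-7, gtol = 1e-10, ftol = 1e-10, max_iter = 100),
    sweep = list(pool_legs = TRUE),
    stats = c(kin_constants(), list(n_boot = 2000, ci_type = "percentile")),
    synthetic = list(n_subjects = 10, speeds = c(0.9, 1.2, 1.5),
                     duration_s = 120, rate = 100, noise_sd = 0.3),
    schema_version = 1)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration (YAML)
#' @param config a `run_config`.
#' @param path file path.
#' @return `read_config()` returns a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Serialize a constrained model to YAML
#'
#' Writes segments (local marker positions, joint-center offsets, scale
#' factors), joints (type, axes, coordinate names, bounds) and the knee
#' prescribed-motion knot table to a YAML file; `read_model_yaml()`
#' rebuilds the model (spline coefficients are recomputed from the
#' knots).
#'
#' @param model a `constrained_model`.
#' @param path file path.
#' @return `read_model_yaml()` returns a `constrained_model`.
#' @export
write_model_yaml <- function(model, path) {
  enc <- list(
    hip_width_factor = model$hip_width_factor,
    pure_hinge_knee = model$pure_hinge_knee,
    scaled = model$scaled,
    knee_knots = model$knee_knots,
    segments = lapply(model$segments, function(s) list(
      name = s$name, side = if (is.na(s$side)) NULL else s$side,
      parent = if (is.na(s$parent)) NULL else s$parent,
      parent_joint = if (is.na(s$parent_joint)) NULL else s$parent_joint,
      origin_in_parent = s$origin_in_parent,
      scale_factors = s$scale_factors,
      markers = lapply(s$markers, as.numeric))),
    joints = lapply(model$joints, function(j) list(
      name = j$name, type = j$type, parent = j$parent, child = j$child,
      axes = as.numeric(j$axes), n_axes = ncol(j$axes),
      coords = j$coords, bounds = as.numeric(j$bounds))))
  yaml::write_yaml(enc, path, precision = 15)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  enc <- yaml::read_yaml(path)
  kk <- lapply(enc$knee_knots, as.numeric)
  model <- structure(list(
    segments = lapply(enc$segments, function(s) list(
      name = s$name, side = if (is.null(s$side)) NA else s$side,
      parent = if (is.null(s$parent)) NA else s$parent,
      parent_joint = if (is.null(s$parent_joint)) NA else s$parent_joint,
      origin_in_parent = as.numeric(s$origin_in_parent),
      markers = lapply(s$markers, as.numeric),
      scale_factors = as.numeric(s$scale_factors))),
    joints = lapply(enc$joints, function(j) {
      k <- j$n_axes
      jt <- list(name = j$name, type = j$type, parent = j$parent,
                 child = j$child,
                 axes = matrix(as.numeric(j$axes), 3, k),
                 coords = as.character(j$coords),
                 bounds = matrix(as.numeric(j$bounds), k, 2),
                 prescribed = NULL)
      if (j$type == "mobile_hinge" && !isTRUE(enc$pure_hinge_knee))
        jt$prescribed <- list(flexion = kk$flexion,
                              ap = nat_spline_prep(kk$flexion, kk$ap),
                              si = nat_spline_prep(kk$flexion, kk$si))
      jt
    }),
    hip_width_factor = enc$hip_width_factor,
    pure_hinge_knee = enc$pure_hinge_knee,
    knee_knots = kk,
    scaled = enc$scaled), class = "constrained_model")
  names(model$segments) <- vapply(model$segments, `[[`, "", "name")
  names(model$joints) <- vapply(model$joints, `[[`, "", "name")
  validate_model(model)
  model
}
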