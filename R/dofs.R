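#' Analyzed degrees of freedom and feature layout
#'
#' The analysis uses 10 rotational degrees of freedom of an upper-body
#' skeletal model: three torso DoFs (flexion = leaning forward, tilt =
#' sideways bend, rotation = axial rotation) and seven DoFs of the dominant
#' arm (shoulder elevation plane, elevation angle and rotation, elbow
#' flexion, forearm rotation, wrist flexion and deviation).
#'
#' Features are laid out DoF-major, metric-minor: for each DoF in
#' [comp_dofs()] order, the four energy metrics in [comp_metrics()] order.
#' Feature names are `<dof>__<metric>`; this order is fixed and is the
#' weight-to-feature correspondence used by [attribute_joints()].
#'
#' @return `comp_dofs()`: character vector of the 10 DoF names.
#' @export
comp_dofs <- function() {
  c("torso_flexion", "torso_tilt", "torso_rotation",
    "elevation_plane", "elevation_angle", "shoulder_rotation",
    "elbow_flexion", "forearm_rotation", "wrist_flexion", "wrist_deviation")
}

#' @rdname comp_dofs
#' @return `comp_metrics()`: character vector of the 4 metric names.
#' @export
comp_metrics <- function() c("jerk", "pow", "eff", "tr")

#' @rdname comp_dofs
#' @param dofs,metrics DoF / metric subsets (defaults: full sets).
#' @return `feature_names()`: character vector of length
#'   `length(dofs) * length(metrics)`, DoF-major.
#' @export
feature_names <- function(dofs = comp_dofs(), metrics = comp_metrics()) {
  as.vector(t(outer(dofs, metrics, function(d, m) paste0(d, "__", m))))
}

# Fixed affine forward map p = A q + p0 from the 10 joint angles to the 3-D
# wrist-marker position (meters). Entries approximate moment arms of an
# adult arm (torso lever ~0.35 m, upper arm ~0.30 m, forearm ~0.25 m,
# wrist/hand ~0.08 m); elbow flexion carries the opposite sign to shoulder
# elevation because flexion retracts the hand while elevation transports it
# forward, so a reach (elevation up, elbow extending) moves the marker in
# one consistent direction. Because the map is linear, marker velocity
# A qdot vanishes exactly when all joint velocities do, which is what ties
# end-effector velocity zero-crossings to joint rests; the sign structure
# keeps every task's amplitude pattern well away from the map's null space
# so mid-motion marker speed stays far above the rest tolerance.
marker_map <- function() {
  A <- rbind(
    #  tflex  ttilt   trot  eplane  eangle  srot   eflex  frot   wflex  wdev
    c( 0.33,  0.05,  0.21,  0.16,  0.24,  0.06, -0.22,  0.05,  0.07,  0.02),
    c( 0.04,  0.31,  0.08,  0.23,  0.12,  0.09,  0.05,  0.07,  0.02,  0.07),
    c( 0.12,  0.07,  0.30,  0.08,  0.27,  0.12, -0.18,  0.08,  0.05,  0.03))
  colnames(A) <- comp_dofs()
  rownames(A) <- c("x", "y", "z")
  A
}

marker_origin <- function() c(x = 0.25, y = 0.10, z = 0.85)

# Per-task joint excursion templates (radians). Each task mainly drives a
# few "task-primary" DoFs; the remaining DoFs carry small incidental motion.
task_amplitudes <- function() {
  d <- comp_dofs()
  base <- setNames(rep(0.03, length(d)), d)
  tasks <- list(
    tray_lift = c(elevation_angle = 0.55, elbow_flexion = 0.75,
                  elevation_plane = 0.10, wrist_flexion = 0.08),
    reach_eye = c(elevation_angle = 0.95, elevation_plane = 0.30,
                  elbow_flexion = -0.50, shoulder_rotation = 0.12),
    reach_chest = c(elevation_angle = 0.60, elevation_plane = 0.40,
                    elbow_flexion = -0.40, shoulder_rotation = 0.10),
    reach_pronation = c(forearm_rotation = 0.90, elevation_angle = 0.45,
                        elbow_flexion = -0.30, wrist_deviation = 0.08),
    reach_supination = c(forearm_rotation = -0.90, elevation_angle = 0.45,
                         elbow_flexion = -0.30, wrist_deviation = -0.08))
  lapply(tasks, function(tt) { a <- base; a[names(tt)] <- tt; a })
}

#' Default acted-compensation conditions
#'
#' Three condition templates emulating commonly observed post-stroke
#' strategies: each attenuates one task-primary arm DoF (attenuation factor
#' `rho`) and recruits one or two normally quiet torso DoFs (recruitment
#' amplitude `delta`, radians). Recruited and impaired sets are disjoint.
#'
#' @return named list of [compensation_spec()] objects (plus the healthy
#'   condition, which has empty recruited/impaired sets).
#' @export
default_conditions <- function() {
  list(
    healthy = compensation_spec("healthy"),
    trunk_lean = compensation_spec(
      "trunk_lean",
      impaired = c(elevation_angle = 0.55),
      recruited = c(torso_flexion = 0.35)),
    trunk_rotation = compensation_spec(
      "trunk_rotation",
      impaired = c(shoulder_rotation = 0.6, elevation_angle = 0.65),
      recruited = c(torso_rotation = 0.32, torso_flexion = 0.12)),
    lateral_lean = compensation_spec(
      "lateral_lean",
      impaired = c(elbow_flexion = 0.5),
      recruited = c(torso_tilt = 0.30)))
}
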