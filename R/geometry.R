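## Task and arm geometry -----------------------------------------------------

#' Task geometry for the robotic evaluation protocol
#'
#' Encodes the target layout of the evaluation tasks: 8 reach targets equally
#' spaced on a circle of 14 cm diameter around the workspace centre for the
#' planar shoulder-elbow robot; 8 wrist pointing targets on an ellipse whose
#' major axis spans 60 degrees of flexion/extension (30 degrees each way) and
#' whose minor axis spans 30 degrees of radial/ulnar deviation; 2 forearm
#' targets at +/- 30 degrees of pronation/supination.
#'
#' @param reach_radius_m Radius of the reach target circle in metres
#'   (default 0.14).
#' @param wrist_major_deg Full major-axis span of the wrist target ellipse in
#'   degrees (default 60).
#' @param wrist_minor_deg Full minor-axis span in degrees (default 30).
#' @param forearm_span_deg Full pronation/supination span in degrees
#'   (default 60).
#' @param target_radius Task tolerance radius, in the task's own units
#'   (metres for reaching, radians for wrist/forearm); default 0.01.
#' @param center Workspace centre (robot centre), default c(0, 0).
#' @return An object of class \code{task_geometry} with target coordinate
#'   lists per task.
#' @export
#' @examples
#' g <- task_geometry()
#' g$reach_targets   # 8 x 2 matrix, metres
task_geometry <- function(reach_radius_m = 0.14, wrist_major_deg = 60,
                          wrist_minor_deg = 30, forearm_span_deg = 60,
                          target_radius = 0.01, center = c(0, 0)) {
  stopifnot(reach_radius_m > 0, wrist_major_deg > 0, wrist_minor_deg > 0,
            forearm_span_deg > 0, target_radius > 0)
  if (target_radius >= reach_radius_m)
    stop("infeasible geometry: target radius must be smaller than the reach radius")
  ang <- seq(0, 2 * pi, length.out = 9)[1:8]
  reach_targets <- cbind(center[1] + reach_radius_m * cos(ang),
                         center[2] + reach_radius_m * sin(ang))
  # wrist targets: semi-axes in radians, F/E on the major axis
  a <- (wrist_major_deg / 2) * pi / 180
  b <- (wrist_minor_deg / 2) * pi / 180
  wrist_targets <- cbind(a * cos(ang), b * sin(ang))
  half <- (forearm_span_deg / 2) * pi / 180
  forearm_targets <- matrix(c(-half, half), ncol = 1)
  structure(list(reach_targets = reach_targets, wrist_targets = wrist_targets,
                 forearm_targets = forearm_targets, center = center,
                 reach_radius_m = reach_radius_m,
                 wrist_major_deg = wrist_major_deg,
                 wrist_minor_deg = wrist_minor_deg,
                 forearm_span_deg = forearm_span_deg,
                 target_radius = target_radius),
            class = "task_geometry")
}

#' Targets for a given task
#' @keywords internal
task_targets <- function(geometry, task) {
  switch(task,
         reach8 = , circle_draw = , resistance = ,
         isometric_hold = geometry$reach_targets,
         wrist_point8 = geometry$wrist_targets,
         forearm_ps = geometry$forearm_targets,
         kinetic_strength = NULL)
}

#' Two-link arm geometry for inverse kinematics
#'
#' Segment lengths and shoulder position of the planar two-link arm model
#' used to estimate shoulder and elbow joint angles from endpoint positions.
#'
#' @param upper_arm_length_m Upper arm (shoulder to elbow) length, metres.
#' @param forearm_length_m Forearm (elbow to hand) length, metres.
#' @param shoulder_position Planar shoulder coordinates, metres. The default
#'   places the shoulder 45 cm behind the workspace centre.
#' @return An object of class \code{arm_geometry}.
#' @export
arm_geometry <- function(upper_arm_length_m = 0.33, forearm_length_m = 0.32,
                         shoulder_position = c(0, -0.45)) {
  stopifnot(upper_arm_length_m > 0, forearm_length_m > 0,
            length(shoulder_position) == 2)
  structure(list(upper_arm_length_m = upper_arm_length_m,
                 forearm_length_m = forearm_length_m,
                 shoulder_position = as.numeric(shoulder_position)),
            class = "arm_geometry")
}

#' Read geometry configuration from YAML or JSON
#'
#' @param path Path to a YAML (.yaml/.yml) or JSON (.json) file whose keys
#'   are arguments of \code{\link{task_geometry}} and, optionally, an
#'   \code{arm} block with arguments of \code{\link{arm_geometry}}.
#' @return List with elements \code{task} (a \code{task_geometry}) and
#'   \code{arm} (an \code{arm_geometry} or NULL).
#' @export
read_geometry_config <- function(path) {
  if (!file.exists(path)) stop("geometry config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  arm_cfg <- cfg$arm
  cfg$arm <- NULL
  task <- do.call(task_geometry, cfg)
  arm <- if (is.null(arm_cfg)) NULL else do.call(arm_geometry, arm_cfg)
  list(task = task, arm = arm)
}
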