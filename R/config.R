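# Structured-text (YAML) round-trip of the full run configuration: arm,
# task, agent and grid sections. Angles cross the file boundary in degrees.

#' Read or write a run configuration file
#'
#' A single YAML document with optional `arm`, `task`, `agent` and `grid`
#' sections covering [arm_params()], [task_config()], [agent_config()] and
#' [experiment_grid()]. Angular quantities (joint limits, spawn box) are
#' written in degrees and converted to radians on read. Missing sections
#' or fields fall back to the package defaults.
#'
#' @param path file path.
#' @return `read_config`: list with elements `arm`, `task`, `agent`,
#'   `grid` (constructed objects). `write_config`: the path, invisibly.
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  arm <- do.call(arm_params, transform_angles_in(doc$arm %||% list()))
  task_args <- doc$task %||% list()
  if (!is.null(task_args$spawn_box_deg)) {
    task_args$spawn_box <- matrix(unlist(task_args$spawn_box_deg), 2, 2,
                                  byrow = TRUE) * pi / 180
    task_args$spawn_box_deg <- NULL
  }
  task <- do.call(task_config, task_args)
  agent <- do.call(agent_config, doc$agent %||% list())
  grid <- if (is.null(doc$grid)) NULL else do.call(experiment_grid, doc$grid)
  list(arm = arm, task = task, agent = agent, grid = grid)
}

transform_angles_in <- function(arm_args) {
  if (!is.null(arm_args$joint_limits_deg)) {
    arm_args$joint_limits <- matrix(unlist(arm_args$joint_limits_deg), 2, 2,
                                    byrow = TRUE) * pi / 180
    arm_args$joint_limits_deg <- NULL
  }
  arm_args
}

#' @rdname read_config
#' @param arm,task,agent objects to serialize (defaults used if `NULL`).
#' @param grid optional [experiment_grid()].
#' @export
write_config <- function(path, arm = arm_params(), task = task_config(),
                         agent = agent_config(), grid = NULL) {
  doc <- list(
    arm = list(L1 = arm$L1, L2 = arm$L2, m1 = arm$m1, m2 = arm$m2,
               c1 = arm$c1, c2 = arm$c2, I1 = arm$I1, I2 = arm$I2,
               joint_limits_deg = list(shoulder = arm$joint_limits[1, ] * 180 / pi,
                                       elbow = arm$joint_limits[2, ] * 180 / pi),
               damping = arm$damping, force_scale = arm$force_scale,
               dt = arm$dt, substeps = arm$substeps),
    task = list(timeout_steps = task$timeout_steps,
                dwell_steps = task$dwell_steps, radius = task$radius,
                spawn_box_deg = list(shoulder = task$spawn_box[1, ] * 180 / pi,
                                     elbow = task$spawn_box[2, ] * 180 / pi),
                step_penalty = task$step_penalty,
                target_reward = task$target_reward,
                activation_penalty_coef = task$activation_penalty_coef,
                reward_mode = task$reward_mode),
    agent = unclass(agent))
  if (!is.null(grid)) doc$grid <- unclass(grid)
  yaml::write_yaml(doc, path)
  invisible(path)
}
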