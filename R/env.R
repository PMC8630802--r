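#' Reaching task configuration
#'
#' Parameters of the goal-conditioned reaching task. Each reach gives the
#' controller `timeout_steps` control steps (50 x 20 ms = 1 s) to bring the
#' endpoint into a circular target of radius `radius` (7.5 cm) and hold it
#' there for `dwell_steps` consecutive steps (5 x 20 ms = 0.1 s). Goal
#' postures are drawn uniformly from the joint-angle spawn box
#' (\[20, 90\] deg at both joints). The per-step reward is
#' `-0.1 + 1*[in target] - 0.245 * sqrt(sum(a_i^2))`: a constant step
#' penalty encouraging fast movement, a target bonus, and a muscle-effort
#' penalty discouraging redundant coactivation.
#'
#' @param timeout_steps reach timeout in control steps (default 50 = 1 s).
#' @param dwell_steps consecutive in-target steps required for success
#'   (default 5 = 0.1 s).
#' @param radius target radius (m), default 0.075.
#' @param spawn_box 2x2 matrix of joint-angle ranges (rad) for goal sampling,
#'   rows = shoulder/elbow, cols = min/max.
#' @param step_penalty constant per-step reward (default -0.1).
#' @param target_reward reward while the endpoint is inside the target
#'   (default 1).
#' @param activation_penalty_coef coefficient of the root-sum-square
#'   activation penalty (default 0.245).
#' @param reward_mode `"per_step"` grants the target bonus every in-target
#'   step (default); `"once"` only on first entry in an episode.
#' @return an object of class `task_config`.
#' @export
task_config <- function(timeout_steps = 50L, dwell_steps = 5L,
                        radius = 0.075,
                        spawn_box = rbind(shoulder = c(20, 90),
                                          elbow    = c(20, 90)) * pi / 180,
                        step_penalty = -0.1, target_reward = 1,
                        activation_penalty_coef = 0.245,
                        reward_mode = c("per_step", "once")) {
  stopifnot(dwell_steps < timeout_steps, dwell_steps >= 1, radius > 0)
  spawn_box <- matrix(as.numeric(spawn_box), 2, 2,
                      dimnames = list(c("shoulder", "elbow"), c("min", "max")))
  cfg <- list(timeout_steps = as.integer(timeout_steps),
              dwell_steps = as.integer(dwell_steps),
              radius = radius, spawn_box = spawn_box,
              step_penalty = step_penalty, target_reward = target_reward,
              activation_penalty_coef = activation_penalty_coef,
              reward_mode = match.arg(reward_mode))
  class(cfg) <- "task_config"
  cfg
}

#' Sample a reach goal
#'
#' Draws a goal posture uniformly and independently per joint over the
#' spawn box and computes its Cartesian endpoint by forward kinematics.
#' Uses R's global random number generator, so a fixed seed replays an
#' identical target sequence.
#'
#' @param params an [arm_params()].
#' @param task a [task_config()].
#' @return a `reach_goal`: list with `theta_goal` (rad), `endpoint_goal`
#'   (m) and `radius` (m).
#' @export
sample_target <- function(params, task = task_config()) {
  box <- task$spawn_box
  theta <- c(stats::runif(1, box[1, 1], box[1, 2]),
             stats::runif(1, box[2, 1], box[2, 2]))
  reach_goal(theta, params, radius = task$radius)
}

#' @rdname sample_target
#' @param theta_goal goal joint angles (rad).
#' @param radius target radius (m).
#' @export
reach_goal <- function(theta_goal, params, radius = 0.075) {
  stopifnot(length(theta_goal) == 2, radius > 0)
  g <- list(theta_goal = as.numeric(theta_goal),
            endpoint_goal = forward_kinematics(as.numeric(theta_goal), params),
            radius = radius)
  class(g) <- "reach_goal"
  g
}

#' Target-acquisition predicate
#'
#' `TRUE` iff the endpoint lies within the target circle, boundary
#' inclusive.
#'
#' @param endpoint Cartesian endpoint (m), 2-vector.
#' @param goal a `reach_goal`.
#' @return logical.
#' @export
reach_success <- function(endpoint, goal) {
  sqrt(sum((endpoint - goal$endpoint_goal)^2)) <= goal$radius
}

#' Per-step reward
#'
#' `r = step_penalty + target_reward * [in_target] - coef * sqrt(sum(a^2))`
#' with the defaults `-0.1 + 1*[in_target] - 0.245*sqrt(sum(a^2))`.
#' The action must already lie in \[0, 1\]^6; the environment clips before
#' calling.
#'
#' @param action 6-vector of muscle activations in \[0, 1\].
#' @param in_target logical.
#' @param task a [task_config()].
#' @return scalar reward.
#' @export
reach_reward <- function(action, in_target, task = task_config()) {
  if (any(action < 0 | action > 1))
    stop("action outside [0, 1]: the environment must clip before reward")
  task$step_penalty + task$target_reward * as.numeric(in_target) -
    task$activation_penalty_coef * sqrt(sum(action^2))
}

#' Goal-conditioned reaching environment
#'
#' Creates an episodic reaching environment wrapping the arm simulator.
#' The returned object is a mutable environment handle used with
#' [env_reset()] and [env_step()]. Observations expose the shoulder and
#' elbow angular positions and velocities plus the goal posture — never the
#' muscle activation states, which are hidden from the controller as they
#' would be in a real FES system.
#'
#' @param params an [arm_params()].
#' @param muscles a muscle table, see [default_muscles()].
#' @param task a [task_config()].
#' @return an object of class `reach_env`.
#' @export
reach_env <- function(params = arm_params(), muscles = default_muscles(),
                      task = task_config()) {
  validate_muscles(muscles)
  e <- new.env(parent = emptyenv())
  e$params <- params; e$muscles <- muscles; e$task <- task
  e$state <- NULL; e$goal <- NULL
  e$steps <- 0L; e$dwell <- 0L; e$active <- FALSE; e$entered <- FALSE
  class(e) <- "reach_env"
  e
}

env_observation <- function(env) {
  list(theta = env$state$theta, omega = env$state$omega,
       theta_goal = env$goal$theta_goal)
}

# numeric vector layout used by the agents: (theta, omega, goal)
obs_vector <- function(obs) c(obs$theta, obs$omega, obs$theta_goal)

#' Start a new reach
#'
#' Begins an episode toward `goal`. With `carry = TRUE` (the training and
#' evaluation convention) the arm keeps the full state — angles, velocities
#' and muscle activations — in which the previous reach ended; targets can
#' therefore spawn on top of the current endpoint. With `carry = FALSE`, or
#' on the first reach of a run, the arm starts at rest at the centre of the
#' spawn box (55 deg at both joints) with zero activations.
#'
#' @param env a [reach_env()].
#' @param goal a `reach_goal`, or `NULL` to sample one.
#' @param carry keep the previous end state as the start state?
#' @return the initial observation: list with `theta`, `omega`, `theta_goal`.
#' @export
env_reset <- function(env, goal = NULL, carry = TRUE) {
  if (is.null(goal)) goal <- sample_target(env$params, env$task)
  if (!carry || is.null(env$state)) {
    mid <- rowMeans(env$task$spawn_box)
    env$state <- arm_state(theta = mid, omega = c(0, 0), act = rep(0, 6))
  }
  env$goal <- goal
  env$steps <- 0L; env$dwell <- 0L; env$active <- TRUE; env$entered <- FALSE
  env_observation(env)
}

#' Advance the environment one control step
#'
#' Clips the action to \[0, 1\]^6, advances the arm dynamics by one 20 ms
#' step, and scores the new state. The episode terminates successfully once
#' the endpoint has stayed inside the target for `dwell_steps` consecutive
#' steps, and is truncated at `timeout_steps` without success.
#'
#' @param env a [reach_env()].
#' @param action 6-vector of commanded muscle activations.
#' @return list with `obs`, `reward`, `terminated`, `truncated`,
#'   `achieved_goal` (the new joint-angle pair) and `in_target`.
#' @export
env_step <- function(env, action) {
  if (!isTRUE(env$active)) stop("env_step called on a finished episode")
  action <- pmin(1, pmax(0, as.numeric(action)))
  env$state <- arm_step(env$state, action, env$params, env$muscles)
  env$steps <- env$steps + 1L

  endpoint <- forward_kinematics(env$state$theta, env$params)
  in_target <- reach_success(endpoint, env$goal)
  env$dwell <- if (in_target) env$dwell + 1L else 0L

  bonus_on <- in_target && (env$task$reward_mode == "per_step" || !env$entered)
  if (in_target) env$entered <- TRUE
  reward <- env$task$step_penalty +
    env$task$target_reward * as.numeric(bonus_on) -
    env$task$activation_penalty_coef * sqrt(sum(action^2))

  terminated <- env$dwell >= env$task$dwell_steps
  truncated <- !terminated && env$steps >= env$task$timeout_steps
  if (terminated || truncated) env$active <- FALSE

  list(obs = env_observation(env), reward = reward,
       terminated = terminated, truncated = truncated,
       achieved_goal = env$state$theta, in_target = in_target)
}
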