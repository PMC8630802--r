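# Evaluation protocol: blocks of consecutive reaches with carry-over start
# states and exploration 0, scored by fraction success and time to target.

new_eval_summary <- function(n_reaches, successes, times, episodes) {
  s <- list(n_reaches = n_reaches,
            fraction_success = mean(successes),
            times_to_target = times,
            successes = successes,
            episodes = episodes)
  class(s) <- "eval_summary"
  s
}

# policy: function(obs_vec) -> action. A block starts at rest in the centre
# of the spawn box and then carries the arm state over between reaches.
evaluate_policy <- function(policy, params, muscles, task,
                            n_reaches = 100L, record_episodes = TRUE) {
  if (n_reaches <= 0) stop("n_reaches must be positive")
  env <- reach_env(params, muscles, task)
  successes <- logical(n_reaches)
  times <- numeric(0)
  episodes <- if (record_episodes) vector("list", n_reaches) else NULL
  obs <- env_reset(env, carry = FALSE)
  for (i in seq_len(n_reaches)) {
    if (i > 1L) obs <- env_reset(env, carry = TRUE)
    rows <- NULL
    repeat {
      a <- policy(obs_vector(obs))
      res <- env_step(env, a)
      if (record_episodes) {
        ep <- forward_kinematics(res$obs$theta, params)
        rows <- rbind(rows, c(res$obs$theta, res$obs$omega, a, ep,
                              as.numeric(res$in_target)))
      }
      obs <- res$obs
      if (res$terminated || res$truncated) {
        successes[i] <- res$terminated
        if (res$terminated)
          times <- c(times, params$dt * (env$steps - task$dwell_steps))
        break
      }
    }
    if (record_episodes) {
      colnames(rows) <- c("theta1", "theta2", "omega1", "omega2",
                          paste0("a", 1:6), "x", "y", "in_target")
      episodes[[i]] <- list(trajectory = rows, goal = env$goal,
                            success = successes[i])
    }
  }
  new_eval_summary(n_reaches, successes, times, episodes)
}

#' Evaluate a frozen controller
#'
#' Runs `n_reaches` consecutive reaches with exploration set to 0 and
#' carry-over start states (the block itself starts at rest in the centre
#' of the spawn box). A reach succeeds when the endpoint dwells inside the
#' target for 0.1 s uninterrupted within the 1 s timeout; for successful
#' reaches the time to target is the simulated time taken to enter the
#' target on the completed dwell, so its maximum is 0.9 s.
#'
#' @param controller a `fes_controller` from [train_controller()], or a
#'   plain policy `function(obs_vec)` returning a 6-vector action (in which
#'   case `params`, `muscles`, `task` must be given).
#' @param n_reaches number of evaluation reaches (default 100).
#' @param radius optionally override the target radius (m).
#' @param params,muscles,task model/task objects; default to those stored
#'   in the controller.
#' @param record_episodes keep per-step trajectories (needed for the
#'   activation analyses and re-scoring sweeps)?
#' @return an `eval_summary`: `n_reaches`, `fraction_success`,
#'   `times_to_target` (s, successful reaches only), `successes`, and
#'   `episodes` (per-reach trajectory records).
#' @export
evaluate <- function(controller, n_reaches = 100L, radius = NULL,
                     params = NULL, muscles = NULL, task = NULL,
                     record_episodes = TRUE) {
  if (inherits(controller, "fes_controller")) {
    params <- params %||% controller$params
    muscles <- muscles %||% controller$muscles
    task <- task %||% controller$task
    policy <- agent_policy(controller$agent)
  } else if (is.function(controller)) {
    if (is.null(params) || is.null(muscles) || is.null(task))
      stop("params, muscles and task are required for a bare policy function")
    policy <- controller
  } else stop("controller must be a fes_controller or a function")
  if (!is.null(radius)) task$radius <- radius
  evaluate_policy(policy, params, muscles, task,
                  n_reaches = n_reaches, record_episodes = record_episodes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Was the controller successfully trained?
#'
#' A controller counts as successfully trained if it acquired at least one
#' target during the evaluation block at the end of training.
#'
#' @param x an `eval_summary` (the final evaluation block) or a
#'   `fes_controller` (its last stored evaluation is used).
#' @return logical.
#' @export
controller_trained <- function(x) {
  if (inherits(x, "fes_controller")) x <- x$evals[[length(x$evals)]]
  stopifnot(inherits(x, "eval_summary"))
  x$fraction_success > 0
}

pool_actions <- function(episodes) {
  if (inherits(episodes, "eval_summary")) episodes <- episodes$episodes
  if (length(episodes) && inherits(episodes[[1]], "eval_summary"))
    episodes <- unlist(lapply(episodes, `[[`, "episodes"), recursive = FALSE)
  if (length(episodes) == 0L) stop("no episodes supplied")
  do.call(rbind, lapply(episodes, function(e)
    e$trajectory[, paste0("a", 1:6), drop = FALSE]))
}

#' Distribution of commanded muscle activations
#'
#' Pools the commanded per-step, per-muscle activation levels across
#' episodes and summarizes how extreme they are: trained controllers tend
#' toward an all-or-nothing strategy, with most commands below 5% or above
#' 95% activation.
#'
#' @param episodes an `eval_summary`, a list of them, or a list of episode
#'   records. Intended to be applied only to controllers exceeding 90%
#'   evaluation success.
#' @param breaks histogram breaks over \[0, 1\].
#' @return list with `counts` (histogram counts), `breaks`, `n`, and
#'   `fraction_extreme` = P(a < 0.05 or a > 0.95).
#' @export
activation_distribution <- function(episodes, breaks = seq(0, 1, by = 0.05)) {
  A <- pool_actions(episodes)
  a <- as.numeric(A)
  h <- graphics::hist(a, breaks = breaks, plot = FALSE)
  list(counts = h$counts, breaks = h$breaks, n = length(a),
       fraction_extreme = mean(a < 0.05 | a > 0.95))
}

#' Distribution of the number of coactivated muscles
#'
#' A muscle counts as active when its commanded relative activation exceeds
#' `active_threshold` (strictly greater than 10% by default). Returns the
#' normalized distribution of the per-time-step count of active muscles.
#'
#' @inheritParams activation_distribution
#' @param active_threshold activation level above which a muscle is active.
#' @return named numeric vector of probabilities over counts `0`..`6`
#'   (sums to 1).
#' @export
coactivation_distribution <- function(episodes, active_threshold = 0.10) {
  A <- pool_actions(episodes)
  counts <- rowSums(A > active_threshold)
  tab <- tabulate(counts + 1L, nbins = 7L)
  stats::setNames(tab / sum(tab), 0:6)
}

# Re-score one recorded trajectory at a new radius using the recorded
# endpoint path and the dwell/timeout rule.
rescore_episode <- function(episode, radius, task) {
  tr <- episode$trajectory
  d <- sqrt((tr[, "x"] - episode$goal$endpoint_goal[1])^2 +
            (tr[, "y"] - episode$goal$endpoint_goal[2])^2)
  inside <- d <= radius
  dwell <- 0L
  for (t in seq_along(inside)) {
    dwell <- if (inside[t]) dwell + 1L else 0L
    if (dwell >= task$dwell_steps)
      return(list(success = TRUE, time = (t - task$dwell_steps)))
  }
  list(success = FALSE, time = NA_real_)
}

#' Generalization sweep over target sizes
#'
#' Evaluates a controller trained on 7.5 cm targets at a series of smaller
#' target radii without retraining. In `"resimulate"` mode (the experiment
#' the controllers were judged by) each radius gets a fresh evaluation
#' block; in `"rescore"` mode the trajectories of a single reference
#' evaluation are re-scored at each radius, which makes the success-region
#' nesting exact: a trajectory succeeding at a small radius necessarily
#' succeeds at every larger one.
#'
#' @param controller a `fes_controller`.
#' @param sizes target radii (m), default the experiment's
#'   `c(0.075, 0.05, 0.025, 0.0125, 0.00625)`.
#' @param n_reaches reaches per radius (resimulate) or in the reference
#'   block (rescore).
#' @param mode `"resimulate"` or `"rescore"`.
#' @param reference optional `eval_summary` with recorded episodes to
#'   re-score (default: computed at the largest radius).
#' @return a `data.frame` with one row per radius: `radius`,
#'   `fraction_success`, `median_time_to_target`, plus (resimulate mode)
#'   the per-radius `eval_summary` objects as an attribute `"evals"`.
#' @export
target_size_sweep <- function(controller,
                              sizes = c(0.075, 0.05, 0.025, 0.0125, 0.00625),
                              n_reaches = 100L,
                              mode = c("resimulate", "rescore"),
                              reference = NULL) {
  if (length(sizes) == 0L) stop("sizes must be non-empty")
  mode <- match.arg(mode)
  task <- controller$task
  if (mode == "resimulate") {
    evals <- lapply(sizes, function(r)
      evaluate(controller, n_reaches = n_reaches, radius = r))
    out <- data.frame(
      radius = sizes,
      fraction_success = vapply(evals, `[[`, numeric(1), "fraction_success"),
      median_time_to_target = vapply(evals, function(e)
        if (length(e$times_to_target)) stats::median(e$times_to_target)
        else NA_real_, numeric(1)))
    attr(out, "evals") <- evals
    out
  } else {
    if (is.null(reference))
      reference <- evaluate(controller, n_reaches = n_reaches,
                            radius = max(sizes))
    rows <- lapply(sizes, function(r) {
      sc <- lapply(reference$episodes, rescore_episode, radius = r, task = task)
      succ <- vapply(sc, `[[`, logical(1), "success")
      times <- controller$params$dt *
        unlist(lapply(sc, function(s) s$time[!is.na(s$time)]))
      data.frame(radius = r, fraction_success = mean(succ),
                 median_time_to_target = if (length(times))
                   stats::median(times) else NA_real_)
    })
    do.call(rbind, rows)
  }
}
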