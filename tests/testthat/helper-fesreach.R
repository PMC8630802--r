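# Shared small objects for the tests. Everything is generated in code;
# seeds are fixed so the suite is deterministic.

default_setup <- function() {
  list(params = arm_params(), muscles = default_muscles(), task = task_config())
}

# A proportional-derivative reference policy: excites each joint's
# monoarticular flexor/extensor by the angle error. Independent of the
# learning code; used as a competent controller where tests need one
# without paying for training.
pd_policy <- function(kp = 5, kd = 0.2) {
  function(x) {
    cmd <- kp * (x[5:6] - x[1:2]) - kd * x[3:4]
    u <- numeric(6)
    u[1] <- max(0, cmd[1]); u[2] <- max(0, -cmd[1])
    u[3] <- max(0, cmd[2]); u[4] <- max(0, -cmd[2])
    pmin(1, u)
  }
}

# Run one episode under a policy function, returning the raw transition
# list in the layout her_relabel() expects.
run_episode <- function(policy, params, muscles, task, goal = NULL,
                        carry = FALSE, env = NULL) {
  if (is.null(env)) env <- reach_env(params, muscles, task)
  obs <- env_reset(env, goal = goal, carry = carry)
  episode <- list()
  repeat {
    a <- policy(c(obs$theta, obs$omega, obs$theta_goal))
    res <- env_step(env, a)
    episode[[length(episode) + 1L]] <-
      list(obs = c(obs$theta, obs$omega), dg = obs$theta_goal, action = a,
           reward = res$reward, next_obs = c(res$obs$theta, res$obs$omega),
           ag = res$achieved_goal, terminated = as.numeric(res$terminated))
    obs <- res$obs
    if (res$terminated || res$truncated) break
  }
  episode
}

random_policy <- function(x) stats::runif(6)

# A synthetic replay-buffer minibatch with valid column layout.
random_batch <- function(n) {
  b <- matrix(stats::rnorm(n * 20), n, 20)
  b[, 7:12] <- matrix(stats::runif(n * 6), n, 6)   # actions in [0,1]
  b[, 20] <- stats::rbinom(n, 1, 0.3)              # done flags
  b
}
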