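#' Learning hyperparameters
#'
#' Configuration for the off-policy actor-critic learners. Actor and critic
#' are feedforward networks with 2 hidden layers of 64 units. Exploration
#' is epsilon-uniform: with probability `exploration_eps` (0.3) an action is
#' drawn uniformly from \[0, 1\]^6, otherwise the deterministic actor output
#' is used. Hindsight experience replay (`use_her`) stores, alongside every
#' transition, `her_k` copies whose goal is replaced by a posture actually
#' achieved later in the same reach ("future" strategy), with the reward
#' recomputed accordingly.
#'
#' @param algorithm `"TD3"` (twin critics, target-policy smoothing, delayed
#'   actor updates) or `"DDPG"`.
#' @param use_her augment the replay buffer with hindsight-relabeled
#'   transitions?
#' @param hidden hidden layer widths (fixed default `c(64, 64)`).
#' @param exploration_eps probability of a uniform random action during
#'   training (0.3; evaluation always uses 0).
#' @param her_k hindsight goals stored per transition (default 4).
#' @param her_strategy relabeling strategy; only `"future"` is implemented.
#' @param gamma discount factor.
#' @param tau soft-update rate for the target networks.
#' @param actor_lr,critic_lr Adam learning rates.
#' @param batch_size minibatch size for gradient updates.
#' @param buffer_capacity replay buffer capacity (FIFO eviction).
#' @param policy_delay TD3: actor/target update period in critic updates.
#' @param target_noise,noise_clip TD3 target-policy smoothing noise scale
#'   and clip, in action units.
#' @param learning_starts environment steps collected before updates begin.
#' @param obs_scale fixed elementwise scaling applied to the 6-dimensional
#'   network input (theta1, theta2, omega1, omega2, goal1, goal2) so that
#'   joint velocities enter on the same order of magnitude as angles.
#' @param seed integer seed controlling every source of randomness
#'   (initialization, targets, exploration, minibatches, smoothing noise).
#' @return an object of class `agent_config`.
#' @export
agent_config <- function(algorithm = c("TD3", "DDPG"),
                         use_her = TRUE,
                         hidden = c(64L, 64L),
                         exploration_eps = 0.3,
                         her_k = 4L,
                         her_strategy = "future",
                         gamma = 0.98,
                         tau = 0.005,
                         actor_lr = 1e-3,
                         critic_lr = 1e-3,
                         batch_size = 128L,
                         buffer_capacity = 1e6,
                         policy_delay = 2L,
                         target_noise = 0.2,
                         noise_clip = 0.5,
                         learning_starts = 1000L,
                         obs_scale = c(1, 1, 1, 1, 1, 1),
                         seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (her_strategy != "future") stop("only the 'future' HER strategy is implemented")
  stopifnot(her_k >= 0, exploration_eps >= 0, exploration_eps <= 1,
            gamma >= 0, gamma <= 1, tau > 0, tau <= 1,
            batch_size >= 1, policy_delay >= 1, length(obs_scale) == 6)
  cfg <- list(algorithm = algorithm, use_her = isTRUE(use_her),
              hidden = as.integer(hidden),
              exploration_eps = exploration_eps,
              her_k = as.integer(her_k), her_strategy = her_strategy,
              gamma = gamma, tau = tau,
              actor_lr = actor_lr, critic_lr = critic_lr,
              batch_size = as.integer(batch_size),
              buffer_capacity = as.integer(buffer_capacity),
              policy_delay = as.integer(policy_delay),
              target_noise = target_noise, noise_clip = noise_clip,
              learning_starts = as.integer(learning_starts),
              obs_scale = as.numeric(obs_scale),
              seed = as.integer(seed))
  class(cfg) <- "agent_config"
  cfg
}

# Buffer column layout: obs(4) dg(2) action(6) reward nobs(4) ag(2) done
BUF_OBS <- 1:4; BUF_DG <- 5:6; BUF_ACT <- 7:12; BUF_REW <- 13L
BUF_NOBS <- 14:17; BUF_AG <- 18:19; BUF_DONE <- 20L

new_buffer <- function(capacity) {
  b <- new.env(parent = emptyenv())
  b$data <- matrix(NA_real_, as.integer(capacity), 20L)
  b$capacity <- as.integer(capacity)
  b$size <- 0L
  b$ptr <- 0L                                  # last written row (FIFO)
  b
}

buffer_push <- function(buf, rows) {
  n <- nrow(rows)
  idx <- ((buf$ptr + seq_len(n) - 1L) %% buf$capacity) + 1L
  buf$data[idx, ] <- rows
  buf$ptr <- (buf$ptr + n) %% buf$capacity
  buf$size <- min(buf$capacity, buf$size + n)
  invisible(buf)
}

buffer_sample <- function(buf, n) {
  idx <- sample.int(buf$size, n, replace = buf$size < n)
  buf$data[idx, , drop = FALSE]
}

transitions_to_rows <- function(trans) {
  t(vapply(trans, function(tr)
    c(tr$obs, tr$dg, tr$action, tr$reward, tr$next_obs, tr$ag, tr$terminated),
    numeric(20L)))
}

new_agent <- function(cfg) {
  in_dim <- 6L; act_dim <- 6L
  asz <- c(in_dim, cfg$hidden, act_dim)
  csz <- c(in_dim + act_dim, cfg$hidden, 1L)
  a <- list(cfg = cfg,
            actor = mlp_init(asz),
            critic1 = mlp_init(csz),
            update_count = 0L)
  if (cfg$algorithm == "TD3") a$critic2 <- mlp_init(csz)
  a$actor_targ <- a$actor
  a$critic1_targ <- a$critic1
  if (cfg$algorithm == "TD3") a$critic2_targ <- a$critic2
  a$actor_opt <- adam_init(a$actor)
  a$critic1_opt <- adam_init(a$critic1)
  if (cfg$algorithm == "TD3") a$critic2_opt <- adam_init(a$critic2)
  a
}

scale_input <- function(X, cfg) {
  if (is.matrix(X)) X * rep(cfg$obs_scale, each = nrow(X)) else X * cfg$obs_scale
}

actor_forward <- function(agent, X) {
  squash(mlp_forward(agent$actor, scale_input(X, agent$cfg)))
}

#' Select an action
#'
#' Maps an observation (joint angles, velocities and goal posture) to a
#' 6-vector of muscle activations in \[0, 1\]. During training
#' (`explore = TRUE`) a fraction `exploration_eps` of actions is drawn
#' uniformly at random over the action space; otherwise the action is the
#' deterministic squashed actor output. Evaluation uses `explore = FALSE`.
#'
#' @param agent an agent as stored in a trained controller.
#' @param obs_vec numeric 6-vector `c(theta, omega, theta_goal)`.
#' @param explore logical.
#' @return 6-vector action.
#' @export
agent_act <- function(agent, obs_vec, explore = FALSE) {
  if (explore && stats::runif(1) < agent$cfg$exploration_eps)
    return(stats::runif(6))
  as.numeric(actor_forward(agent, matrix(obs_vec, 1L)))
}

# Temporal-difference target y = r + gamma * (1 - done) * Q'(s', pi'(s')).
# For TD3 the bootstrap uses the minimum of the twin target critics and a
# smoothed (noisy, clipped) target action.
td_target <- function(agent, R, S2, D) {
  cfg <- agent$cfg
  X2 <- scale_input(S2, cfg)
  a2 <- squash(mlp_forward(agent$actor_targ, X2))
  if (cfg$algorithm == "TD3") {
    n <- length(a2)
    noise <- pmin(pmax(stats::rnorm(n, 0, cfg$target_noise),
                       -cfg$noise_clip), cfg$noise_clip)
    a2 <- pmin(pmax(a2 + noise, 0), 1)
    q1 <- mlp_forward(agent$critic1_targ, cbind(X2, a2))
    q2 <- mlp_forward(agent$critic2_targ, cbind(X2, a2))
    qn <- pmin(q1, q2)
  } else {
    qn <- mlp_forward(agent$critic1_targ, cbind(X2, a2))
  }
  R + cfg$gamma * (1 - D) * qn
}

critic_regress <- function(agent, which, Xc, y) {
  net <- agent[[which]]; opt <- agent[[paste0(which, "_opt")]]
  fwd <- mlp_forward(net, Xc, cache = TRUE)
  err <- fwd$out - y
  grads <- mlp_backward(net, fwd, 2 * err / length(err))
  st <- adam_step(net, grads, opt, agent$cfg$critic_lr)
  agent[[which]] <- st$net; agent[[paste0(which, "_opt")]] <- st$opt
  list(agent = agent, loss = mean(err^2))
}

actor_ascend <- function(agent, X) {
  n <- nrow(X)
  fa <- mlp_forward(agent$actor, X, cache = TRUE)
  a <- squash(fa$out)
  fc <- mlp_forward(agent$critic1, cbind(X, a), cache = TRUE)
  # gradient of -mean(Q) through the critic input into the actor
  gc <- mlp_backward(agent$critic1, fc, matrix(-1 / n, n, 1L))
  dA <- gc$dX[, 7:12, drop = FALSE] * dsquash(a)
  ga <- mlp_backward(agent$actor, fa, dA)
  st <- adam_step(agent$actor, ga, agent$actor_opt, agent$cfg$actor_lr)
  agent$actor <- st$net; agent$actor_opt <- st$opt
  list(agent = agent, loss = -mean(fc$out))
}

unpack_batch <- function(batch, cfg) {
  list(S  = cbind(batch[, BUF_OBS, drop = FALSE], batch[, BUF_DG, drop = FALSE]),
       A  = batch[, BUF_ACT, drop = FALSE],
       R  = batch[, BUF_REW],
       S2 = cbind(batch[, BUF_NOBS, drop = FALSE], batch[, BUF_DG, drop = FALSE]),
       D  = batch[, BUF_DONE])
}

#' One DDPG gradient update
#'
#' Regresses the critic toward the one-step temporal-difference target
#' `y = r + gamma (1 - done) Q'(s', pi'(s'))` computed with the slow-moving
#' target networks, ascends the actor on `Q(s, pi(s))`, and soft-updates
#' the target networks with rate `tau`.
#'
#' @param agent the agent state.
#' @param batch a sampled minibatch (rows of the replay buffer).
#' @return list with updated `agent`, `critic_loss`, `actor_loss`.
#' @export
ddpg_update <- function(agent, batch) {
  if (is.null(batch) || nrow(batch) == 0L) stop("empty batch")
  cfg <- agent$cfg
  bb <- unpack_batch(batch, cfg)
  y <- td_target(agent, bb$R, bb$S2, bb$D)
  X <- scale_input(bb$S, cfg)
  cr <- critic_regress(agent, "critic1", cbind(X, bb$A), y)
  agent <- cr$agent
  ac <- actor_ascend(agent, X)
  agent <- ac$agent
  agent$actor_targ <- soft_update(agent$actor_targ, agent$actor, cfg$tau)
  agent$critic1_targ <- soft_update(agent$critic1_targ, agent$critic1, cfg$tau)
  agent$update_count <- agent$update_count + 1L
  list(agent = agent, critic_loss = cr$loss, actor_loss = ac$loss)
}

#' One TD3 gradient update
#'
#' Both critics are regressed toward the clipped double-Q target
#' `y = r + gamma (1 - done) min(Q1', Q2')(s', pi'(s') + clipped noise)`.
#' The actor and all three target networks are updated only every
#' `policy_delay`-th call, counted by `step_index`.
#'
#' @inheritParams ddpg_update
#' @param step_index integer update counter used for the delay schedule.
#' @return list with updated `agent`, `critic_loss`, `actor_loss`
#'   (`NA` when the actor is not updated on this call).
#' @export
td3_update <- function(agent, batch, step_index) {
  if (is.null(batch) || nrow(batch) == 0L) stop("empty batch")
  cfg <- agent$cfg
  bb <- unpack_batch(batch, cfg)
  y <- td_target(agent, bb$R, bb$S2, bb$D)
  X <- scale_input(bb$S, cfg)
  Xc <- cbind(X, bb$A)
  c1 <- critic_regress(agent, "critic1", Xc, y); agent <- c1$agent
  c2 <- critic_regress(agent, "critic2", Xc, y); agent <- c2$agent
  actor_loss <- NA_real_
  if (step_index %% cfg$policy_delay == 0L) {
    ac <- actor_ascend(agent, X)
    agent <- ac$agent; actor_loss <- ac$loss
    agent$actor_targ <- soft_update(agent$actor_targ, agent$actor, cfg$tau)
    agent$critic1_targ <- soft_update(agent$critic1_targ, agent$critic1, cfg$tau)
    agent$critic2_targ <- soft_update(agent$critic2_targ, agent$critic2, cfg$tau)
  }
  agent$update_count <- agent$update_count + 1L
  list(agent = agent, critic_loss = (c1$loss + c2$loss) / 2,
       actor_loss = actor_loss)
}

#' Hindsight goal relabeling ("future" strategy)
#'
#' For every transition of a finished reach, emits the original transition
#' plus `k` relabeled copies. Each copy's desired goal is replaced by the
#' posture actually achieved at a uniformly sampled later step of the same
#' reach (the final transition is relabeled with its own achieved state).
#' The reward and termination flag of a relabeled copy are recomputed from
#' the success predicate — comparing the forward-kinematic endpoints of the
#' achieved and relabeled goal postures against the target radius — and the
#' reward formula with the original action.
#'
#' @param episode list of transitions, each a list with fields `obs`
#'   (theta, omega), `dg` (desired goal posture), `action`, `reward`,
#'   `next_obs`, `ag` (achieved posture after the step), `terminated`.
#' @param k number of hindsight copies per transition (`k = 0` returns the
#'   episode unchanged).
#' @param params an [arm_params()] (for forward kinematics).
#' @param task a [task_config()] (radius and reward coefficients).
#' @return flat list of transitions, length `(k + 1) * length(episode)`.
#' @export
her_relabel <- function(episode, k, params, task) {
  if (length(episode) == 0L) stop("empty episode")
  if (k < 0) stop("k must be >= 0")
  if (k == 0L) return(episode)
  T_ <- length(episode)
  ep_ag <- lapply(episode, function(tr) forward_kinematics(tr$ag, params))
  out <- vector("list", (k + 1L) * T_)
  pos <- 1L
  for (t in seq_len(T_)) {
    tr <- episode[[t]]
    out[[pos]] <- tr; pos <- pos + 1L
    for (j in seq_len(k)) {
      src <- if (t == T_) T_ else t - 1L + sample.int(T_ - t + 1L, 1L)
      new_dg <- episode[[src]]$ag
      in_target <- sqrt(sum((ep_ag[[t]] - forward_kinematics(new_dg, params))^2)) <= task$radius
      r <- task$step_penalty + task$target_reward * as.numeric(in_target) -
        task$activation_penalty_coef * sqrt(sum(tr$action^2))
      tr2 <- tr
      tr2$dg <- new_dg; tr2$reward <- r; tr2$terminated <- as.numeric(in_target)
      out[[pos]] <- tr2; pos <- pos + 1L
    }
  }
  out
}

agent_policy <- function(agent) {
  force(agent)
  function(obs_vec) agent_act(agent, obs_vec, explore = FALSE)
}

#' Train a reaching controller
#'
#' The main fitting function: trains a goal-conditioned reaching controller
#' on the planar musculoskeletal arm with DDPG or TD3, optionally with
#' hindsight experience replay. Reaches are run back-to-back with
#' carry-over start states; finished reaches are stored in the replay
#' buffer (plus hindsight relabelings when enabled) and one gradient update
#' is performed per environment step once `learning_starts` transitions
#' have been collected. Every `eval_every` steps (default 15,000 steps =
#' 5 simulated minutes) and at the end of training, the greedy policy is
#' evaluated for `eval_reaches` reaches with exploration 0.
#'
#' All randomness — network initialization, target sampling, exploration,
#' minibatch sampling, hindsight goal choice, TD3 smoothing noise — is
#' driven by R's RNG seeded with `config$seed`, so a rerun with the same
#' configuration reproduces the learning curve exactly.
#'
#' @param params an [arm_params()].
#' @param muscles a muscle table, see [default_muscles()].
#' @param task a [task_config()].
#' @param config an [agent_config()].
#' @param total_steps number of 20 ms environment steps to train for
#'   (100,000 = 2,000 s of simulated movement).
#' @param eval_every evaluation period in environment steps.
#' @param eval_reaches reaches per evaluation block.
#' @param verbose print a line per evaluation block?
#' @return an object of class `fes_controller`: the trained agent plus the
#'   learning curve (`$curve`), the evaluation summaries (`$evals`), and
#'   the model/task configuration used.
#' @seealso [evaluate()], [target_size_sweep()], [run_grid()]
#' @export
train_controller <- function(params = arm_params(),
                             muscles = default_muscles(),
                             task = task_config(),
                             config = agent_config(),
                             total_steps = 100000L,
                             eval_every = 15000L,
                             eval_reaches = 100L,
                             verbose = FALSE) {
  if (total_steps <= 0) stop("total_steps must be positive")
  set.seed(config$seed)
  agent <- new_agent(config)
  buf <- new_buffer(config$buffer_capacity)
  env <- reach_env(params, muscles, task)
  obs <- env_reset(env, carry = FALSE)
  episode <- list()
  evals <- list()
  curve <- NULL

  for (step in seq_len(total_steps)) {
    a <- agent_act(agent, obs_vector(obs), explore = TRUE)
    res <- env_step(env, a)
    episode[[length(episode) + 1L]] <-
      list(obs = c(obs$theta, obs$omega), dg = obs$theta_goal, action = a,
           reward = res$reward, next_obs = c(res$obs$theta, res$obs$omega),
           ag = res$achieved_goal, terminated = as.numeric(res$terminated))
    obs <- res$obs
    if (res$terminated || res$truncated) {
      trans <- if (config$use_her)
        her_relabel(episode, config$her_k, params, task) else episode
      buffer_push(buf, transitions_to_rows(trans))
      episode <- list()
      obs <- env_reset(env, carry = TRUE)
    }
    if (buf$size >= max(config$learning_starts, config$batch_size)) {
      batch <- buffer_sample(buf, config$batch_size)
      upd <- if (config$algorithm == "TD3")
        td3_update(agent, batch, agent$update_count + 1L)
      else ddpg_update(agent, batch)
      agent <- upd$agent
    }
    if (step %% eval_every == 0L || step == total_steps) {
      ev <- evaluate_policy(agent_policy(agent), params, muscles, task,
                            n_reaches = eval_reaches)
      evals[[length(evals) + 1L]] <- ev
      curve <- rbind(curve, data.frame(
        step = step,
        sim_minutes = step * params$dt / 60,
        fraction_success = ev$fraction_success,
        median_time_to_target = if (length(ev$times_to_target))
          stats::median(ev$times_to_target) else NA_real_))
      if (verbose)
        message(sprintf("step %d (%.1f sim min): success %.2f", step,
                        step * params$dt / 60, ev$fraction_success))
      if (step == total_steps) break
    }
  }

  ctrl <- list(agent = agent, config = config, params = params,
               muscles = muscles, task = task,
               total_steps = as.integer(total_steps),
               curve = curve, evals = evals,
               buffer_size = buf$size)
  class(ctrl) <- "fes_controller"
  ctrl
}

#' Save or load a trained controller
#'
#' Checkpoints serialize the full controller object (networks, optimizer
#' state, configuration and learning curve) with a format version tag;
#' loading reproduces `predict()` output bitwise.
#'
#' @param controller a `fes_controller`.
#' @param path file path for the checkpoint.
#' @return `load_controller` returns the controller, invisibly for save.
#' @export
save_controller <- function(controller, path) {
  stopifnot(inherits(controller, "fes_controller"))
  saveRDS(list(format = "fesreach-checkpoint-1", controller = controller), path)
  invisible(path)
}

#' @rdname save_controller
#' @export
load_controller <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "fesreach-checkpoint-1"))
    stop("not a fesreach checkpoint")
  x$controller
}
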