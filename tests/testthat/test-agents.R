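test_that("actions are bounded, deterministic without exploration, and
           epsilon-uniform with it", {
  set.seed(10)
  ag <- fesreach:::new_agent(agent_config(algorithm = "TD3", seed = 10))
  x <- c(1, 1, 0, 0, 0.8, 0.9)
  a1 <- agent_act(ag, x, explore = FALSE)
  a2 <- agent_act(ag, x, explore = FALSE)
  expect_identical(a1, a2)
  expect_true(all(a1 >= 0 & a1 <= 1))
  # with exploration, the fraction of uniform-random actions is 0.30
  set.seed(11)
  n <- 1e5
  greedy <- agent_act(ag, x, explore = FALSE)
  acts <- matrix(0, n, 6)
  for (i in seq_len(n)) acts[i, ] <- agent_act(ag, x, explore = TRUE)
  frac_random <- mean(acts[, 1] != greedy[1])
  expect_lt(abs(frac_random - 0.30), 0.01)
  expect_true(all(acts >= 0 & acts <= 1))
})

test_that("DDPG TD target reduces to the reward in the gamma = 0 limit", {
  set.seed(12)
  ag <- fesreach:::new_agent(agent_config(algorithm = "DDPG", gamma = 0))
  R <- rnorm(32); S2 <- matrix(rnorm(32 * 6), 32, 6); D <- rbinom(32, 1, 0.5)
  y <- fesreach:::td_target(ag, R, S2, D)
  expect_equal(as.numeric(y), R)
})

test_that("tau = 1 makes target networks equal online networks after one update", {
  set.seed(13)
  ag <- fesreach:::new_agent(agent_config(algorithm = "DDPG", tau = 1))
  batch <- random_batch(64)
  ag2 <- ddpg_update(ag, batch)$agent
  expect_identical(ag2$actor_targ, ag2$actor)
  expect_identical(ag2$critic1_targ, ag2$critic1)
})

test_that("critic regresses to the reward on a single terminal transition", {
  set.seed(14)
  ag <- fesreach:::new_agent(agent_config(algorithm = "DDPG", critic_lr = 1e-2))
  obs <- c(1, 1, 0, 0); dg <- c(0.9, 0.9); a <- runif(6); r <- 0.62
  row <- c(obs, dg, a, r, obs, c(1, 1), 1)   # terminated: no bootstrap
  batch <- matrix(rep(row, 64), 64, 20, byrow = TRUE)
  for (i in 1:500) ag <- ddpg_update(ag, batch)$agent
  X <- fesreach:::scale_input(matrix(c(obs, dg), 1), ag$cfg)
  q <- fesreach:::mlp_forward(ag$critic1, cbind(X, matrix(a, 1)))
  expect_equal(as.numeric(q), r, tolerance = 1e-2)
})

test_that("TD3 twin-minimum target never exceeds either critic's own target", {
  set.seed(15)
  cfg <- agent_config(algorithm = "TD3", target_noise = 0)
  ag <- fesreach:::new_agent(cfg)
  S2 <- matrix(rnorm(64 * 6), 64, 6)
  X2 <- fesreach:::scale_input(S2, cfg)
  a2 <- fesreach:::squash(fesreach:::mlp_forward(ag$actor_targ, X2))
  q1 <- fesreach:::mlp_forward(ag$critic1_targ, cbind(X2, a2))
  q2 <- fesreach:::mlp_forward(ag$critic2_targ, cbind(X2, a2))
  y <- fesreach:::td_target(ag, rep(0, 64), S2, rep(0, 64))
  expect_true(all(y <= ag$cfg$gamma * q1 + 1e-12))
  expect_true(all(y <= ag$cfg$gamma * q2 + 1e-12))
  # identical twins reduce the target to the single-critic (DDPG) target
  ag$critic2_targ <- ag$critic1_targ
  y2 <- fesreach:::td_target(ag, rep(0, 64), S2, rep(0, 64))
  expect_equal(as.numeric(y2), as.numeric(ag$cfg$gamma * q1))
})

test_that("TD3 delays actor and target updates by policy_delay", {
  set.seed(16)
  ag <- fesreach:::new_agent(agent_config(algorithm = "TD3", policy_delay = 2))
  batch <- random_batch(32)
  actor0 <- ag$actor
  u1 <- td3_update(ag, batch, step_index = 1)   # odd: critics only
  expect_identical(u1$agent$actor, actor0)
  expect_true(is.na(u1$actor_loss))
  u2 <- td3_update(u1$agent, batch, step_index = 2)
  expect_false(identical(u2$agent$actor, actor0))
  expect_false(is.na(u2$actor_loss))
})

test_that("updates reject an empty batch", {
  set.seed(17)
  agT <- fesreach:::new_agent(agent_config(algorithm = "TD3"))
  agD <- fesreach:::new_agent(agent_config(algorithm = "DDPG"))
  empty <- matrix(numeric(0), 0, 20)
  expect_error(td3_update(agT, empty, 1), "empty")
  expect_error(ddpg_update(agD, empty), "empty")
})

test_that("replay buffer caps at capacity with FIFO eviction", {
  buf <- fesreach:::new_buffer(10)
  rows <- matrix(seq_len(20 * 14), 14, 20)   # 14 rows, values identify order
  fesreach:::buffer_push(buf, rows[1:6, ])
  expect_equal(buf$size, 6L)
  fesreach:::buffer_push(buf, rows[7:14, ])
  expect_equal(buf$size, 10L)
  # the four oldest rows (1-4) were evicted by wraparound
  stored_first <- sort(buf$data[, 1])
  expect_equal(stored_first, sort(rows[5:14, 1]))
})

test_that("HER relabeling recomputes rewards from the success predicate", {
  su <- default_setup()
  set.seed(18)
  ep <- run_episode(random_policy, su$params, su$muscles, su$task)
  expect_identical(her_relabel(ep, 0, su$params, su$task), ep)
  out <- her_relabel(ep, 4, su$params, su$task)
  expect_length(out, 5 * length(ep))
  for (tr in out) {
    d <- sqrt(sum((forward_kinematics(tr$ag, su$params) -
                   forward_kinematics(tr$dg, su$params))^2))
    in_target <- d <= su$task$radius
    if (tr$terminated == 1 || !identical(tr$dg, ep[[1]]$dg)) {
      expect_equal(tr$reward,
                   -0.1 + as.numeric(in_target) - 0.245 * sqrt(sum(tr$action^2)))
    }
  }
  expect_error(her_relabel(ep, -1, su$params, su$task), "k")
  expect_error(her_relabel(list(), 4, su$params, su$task), "empty")
})

test_that("HER future strategy only borrows goals achieved later in the reach", {
  su <- default_setup()
  set.seed(19)
  ep <- run_episode(random_policy, su$params, su$muscles, su$task)
  T_ <- length(ep)
  ags <- lapply(ep, `[[`, "ag")
  out <- her_relabel(ep, 3, su$params, su$task)
  for (t in seq_len(T_)) {
    block <- out[((t - 1) * 4 + 2):((t - 1) * 4 + 4)]
    for (tr in block) {
      src <- which(vapply(ags, identical, logical(1), tr$dg))
      expect_true(any(src >= t))
    }
  }
  # the final transition is relabeled with its own achieved state: a success
  last <- out[[4 * T_]]
  expect_identical(last$dg, ep[[T_]]$ag)
  expect_equal(last$terminated, 1)
  expect_equal(last$reward, 0.9 - 0.245 * sqrt(sum(last$action^2)))
})

test_that("checkpoints round-trip the policy bitwise", {
  set.seed(20)
  ctrl <- train_controller(config = agent_config(seed = 20, learning_starts = 100,
                                                 batch_size = 32),
                           total_steps = 300, eval_every = 300, eval_reaches = 2)
  path <- tempfile(fileext = ".rds")
  save_controller(ctrl, path)
  ctrl2 <- load_controller(path)
  x <- c(1, 1, 0.2, -0.1, 0.8, 0.9)
  expect_identical(predict(ctrl, x), predict(ctrl2, x))
  unlink(path)
})

test_that("training rejects nonpositive step budgets", {
  expect_error(train_controller(total_steps = 0), "positive")
})
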