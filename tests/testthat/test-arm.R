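test_that("forward kinematics matches the planar geometry", {
  p <- arm_params()
  expect_equal(forward_kinematics(c(0, 0), p), c(p$L1 + p$L2, 0))
  expect_equal(forward_kinematics(c(pi / 2, 0), p), c(0, p$L1 + p$L2),
               tolerance = 1e-12)
  expect_equal(forward_kinematics(c(pi / 2, pi / 2), p), c(-p$L2, p$L1),
               tolerance = 1e-12)
  # matrix input agrees with vector input row by row
  th <- matrix(runif(10, 0, pi), 5, 2)
  M <- forward_kinematics(th, p)
  for (i in 1:5)
    expect_equal(unname(M[i, ]), forward_kinematics(th[i, ], p))
})

test_that("muscle kinematics follows constant-moment-arm excursion", {
  p <- arm_params(); m <- default_muscles()
  s0 <- arm_state(theta = c(0.5, 0.7), omega = c(0, 0))
  mk0 <- muscle_kinematics(s0, m)
  expect_equal(mk0$velocity, rep(0, 6))
  # a muscle not crossing the elbow keeps its length when only theta2 moves
  s1 <- arm_state(theta = c(0.5, 1.2))
  mk1 <- muscle_kinematics(s1, m)
  mono_sh <- which(m$r_elbow == 0)
  expect_equal(mk1$length[mono_sh], mk0$length[mono_sh])
  # velocity is minus moment arm times joint velocity
  s2 <- arm_state(theta = c(0.5, 0.7), omega = c(1, 0))
  mk2 <- muscle_kinematics(s2, m)
  expect_equal(mk2$velocity, -m$r_shoulder)
})

test_that("Hill muscle forces obey the activation and scaling contract", {
  p <- arm_params(); m <- default_muscles()
  ref <- c(55, 55) * pi / 180   # posture where all muscles sit at l_opt
  s_off <- arm_state(theta = ref, act = rep(0, 6))
  expect_equal(muscle_forces(s_off, m, p), rep(0, 6))
  s_on <- arm_state(theta = ref, act = rep(1, 6))
  expect_equal(muscle_forces(s_on, m, p), m$Fmax)
  p50 <- set_force_scale(p, 0.5)
  expect_equal(muscle_forces(s_on, m, p50), m$Fmax / 2)
  # forces never negative, even at high lengthening/shortening speeds
  for (om in list(c(30, 0), c(-30, 0), c(0, 40), c(-15, -25))) {
    s <- arm_state(theta = ref, omega = om, act = runif(6))
    expect_true(all(muscle_forces(s, m, p) >= 0))
  }
})

test_that("joint torques equal the brute-force sum over muscles", {
  p <- arm_params(); m <- default_muscles()
  expect_equal(joint_torques(rep(0, 6), m), c(0, 0))
  m1 <- m; m1$r_shoulder <- c(0.03, rep(0, 5)); m1$r_elbow <- rep(0, 6)
  expect_equal(joint_torques(c(100, rep(0, 5)), m1), c(3, 0))
  # independent oracle: accumulate torque muscle by muscle in a plain loop
  set.seed(42)
  for (rep in 1:20) {
    mm <- m
    mm$r_shoulder <- runif(6, -0.05, 0.05)
    mm$r_elbow <- runif(6, -0.05, 0.05)
    f <- runif(6, 0, 1500)
    tau_oracle <- c(0, 0)
    for (i in 1:6)
      tau_oracle <- tau_oracle + f[i] * c(mm$r_shoulder[i], mm$r_elbow[i])
    expect_equal(joint_torques(f, mm), tau_oracle)
  }
  # equal flexor/extensor forces on opposite equal moment arms cancel
  m2 <- m; m2$r_shoulder <- c(0.03, -0.03, rep(0, 4)); m2$r_elbow <- rep(0, 6)
  expect_equal(joint_torques(c(200, 200, rep(0, 4)), m2), c(0, 0))
})

test_that("activation dynamics Euler step saturates as specified", {
  p <- arm_params(); m <- default_muscles()
  # u=1 from a=0 with tau_act=15 ms and dt=20 ms overshoots and clips to 1
  s <- arm_state(theta = c(1, 1), act = rep(0, 6))
  s1 <- arm_step(s, rep(1, 6), p, m)
  expect_equal(s1$act, rep(1, 6))
  # equilibrium: excitation equal to activation, zero velocity, zero torque
  s_eq <- arm_state(theta = c(1, 1), omega = c(0, 0), act = rep(0, 6))
  s_eq2 <- arm_step(s_eq, rep(0, 6), p, m)
  expect_equal(s_eq2$theta, s_eq$theta)
  expect_equal(s_eq2$omega, c(0, 0))
  expect_equal(s_eq2$act, rep(0, 6))
})

test_that("step is deterministic and clips out-of-range excitation", {
  p <- arm_params(); m <- default_muscles()
  s <- arm_state(theta = c(0.8, 1.1), omega = c(0.5, -0.2), act = runif(6))
  u <- runif(6)
  expect_identical(arm_step(s, u, p, m), arm_step(s, u, p, m))
  expect_warning(s2 <- arm_step(s, c(2, -1, 0.5, 0.5, 0.5, 0.5), p, m),
                 "clipped")
  s3 <- suppressWarnings(arm_step(s, c(1, 0, 0.5, 0.5, 0.5, 0.5), p, m))
  expect_identical(s2, s3)
})

test_that("activations stay in [0,1] and decay passively", {
  p <- arm_params(); m <- default_muscles()
  set.seed(3)
  s <- arm_state(theta = c(1, 1))
  for (i in 1:100) {
    s <- arm_step(s, runif(6, -0.2, 1.2) |> pmin(1) |> pmax(0), p, m)
    expect_true(all(s$act >= 0 & s$act <= 1))
  }
  # passive decay: with zero excitation activations decrease monotonically
  prev <- s$act
  for (i in 1:50) {
    s <- arm_step(s, rep(0, 6), p, m)
    expect_true(all(s$act <= prev + 1e-15))
    prev <- s$act
  }
  expect_true(all(prev < 1e-3))
})

test_that("endpoint stays in the reachable annulus under random control", {
  p <- arm_params(); m <- default_muscles()
  set.seed(4)
  s <- arm_state(theta = c(1, 1))
  for (i in 1:200) {
    s <- arm_step(s, runif(6), p, m)
    r <- sqrt(sum(forward_kinematics(s$theta, p)^2))
    expect_true(r >= abs(p$L1 - p$L2) - 1e-12 && r <= p$L1 + p$L2 + 1e-12)
    expect_true(all(s$theta >= p$joint_limits[, 1] - 1e-12))
    expect_true(all(s$theta <= p$joint_limits[, 2] + 1e-12))
  }
})

test_that("force_scale validation rejects degenerate values", {
  p <- arm_params()
  expect_equal(set_force_scale(p, 1.0)$force_scale, 1.0)
  expect_equal(set_force_scale(p, 0.5)$force_scale, 0.5)
  expect_error(set_force_scale(p, 0))
  expect_error(set_force_scale(p, -0.2))
  expect_error(set_force_scale(p, 1.5))
})

test_that("fifty 20 ms steps cover one second of simulated time", {
  p <- arm_params()
  expect_equal(50 * p$dt, 1.0)
  expect_equal(task_config()$timeout_steps, 50L)
})
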