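Package: fesreach
Title: Reinforcement Learning Controllers for a Planar Musculoskeletal Arm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a horizontal-plane two-joint human arm driven by six
    Hill-type muscle actuators and trains goal-conditioned reaching
    controllers for it with off-policy actor-critic reinforcement learning
    (DDPG and TD3), optionally augmented with hindsight experience replay.
    Intended as a testbed for functional electrical stimulation (FES)
    control strategies: the controller observes only joint kinematics and a
    goal posture, never the internal actuator states. Includes the episodic
    reaching environment with a sparse-plus-effort-penalty reward,
    evaluation metrics (fraction of successful reaches, time to target,
    fraction of controllers trained, muscle activation and coactivation
    distributions), target-size generalization sweeps, and an experiment
    grid runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
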