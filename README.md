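# fesreach

Reinforcement-learning controllers for a planar musculoskeletal model of
the human arm.

## The problem

Functional electrical stimulation (FES) can restore arm movement to people
with high-level spinal cord injury by electrically activating paralyzed
muscles, but it needs a controller that turns a desired goal posture into
coordinated stimulation of redundant, nonlinear, history-dependent muscle
actuators — using only easily observable signals (joint kinematics), never
the internal state of the muscles. `fesreach` is a simulation testbed for
that controller-design problem, aimed at motor-control and neural
engineering researchers.

It provides:

* **A musculoskeletal arm simulator** — two rigid segments on a
  frictionless horizontal plane (no gravity), two pin joints, and six
  Hill-type muscle actuators (four monoarticular, two biarticular:
  anterior/posterior deltoid, brachialis, triceps short head, biceps,
  triceps long head), integrated by forward Euler at 20 ms. A global
  force scale emulates atrophied muscle (e.g. 50% of able-bodied forces).
* **A goal-conditioned reaching task** — targets of radius 7.5 cm drawn
  uniformly in the joint box [20°, 90°]², a 1 s timeout with a 0.1 s
  dwell requirement, carry-over start states, and the per-step reward

  $$ r_t = -0.1 \;+\; 1\cdot[\text{in target}] \;-\; 0.245\sqrt{\sum_i a_i^2}, $$

  where $a \in [0,1]^6$ is the commanded muscle activation vector.
* **Off-policy actor-critic learners** — DDPG and TD3 (2×64 ReLU networks,
  ε-uniform exploration at 0.3), optionally with **hindsight experience
  replay** (HER, "future" strategy, k = 4), implemented from scratch in
  base R with fully seeded determinism.
* **The evaluation protocol** — 100-reach evaluation blocks with
  exploration 0: fraction success, time to target (≤ 0.9 s by
  construction), fraction of controllers successfully trained, activation
  and coactivation distributions, and target-size generalization sweeps
  down to 0.625 cm without retraining.

## A worked example

Train a TD3 + HER controller for 30,000 steps (10 simulated minutes of
arm movement — single-seed runs converge around here) and inspect it:

```r
library(fesreach)

ctrl <- train_controller(
  config      = agent_config(algorithm = "TD3", use_her = TRUE, seed = 104),
  total_steps = 30000, eval_every = 15000, eval_reaches = 100)
print(ctrl)
#> Reaching controller for the planar 6-muscle arm
#>   algorithm: TD3 + HER
#>   trained for 30000 steps (10.0 simulated minutes), force scale 1.00
#>   final evaluation: 100% of 100 reaches successful, median time to target 0.16 s
```

All 100 evaluation reaches acquired the 7.5 cm target, with a median of
0.16 s from reach onset to the target entry that began the successful
dwell — comparable to able-bodied reach times for targets of this size.
Now ask how far the same frozen policy generalizes to smaller targets it
never trained on:

```r
set.seed(7)
target_size_sweep(ctrl, n_reaches = 100)
#>    radius fraction_success median_time_to_target
#> 1 0.07500             1.00                  0.14
#> 2 0.05000             0.98                  0.30
#> 3 0.02500             0.59                  0.64
#> 4 0.01250             0.11                  0.64
#> 5 0.00625             0.00                    NA
```

Accuracy degrades gracefully to 5 cm targets, then collapses below
2.5 cm: the controller learned to reach *regions*, not points, and it
trades speed for accuracy as the target shrinks (note the rising times).
`plot(ctrl)` draws the learning curve; `predict(ctrl, obs)` returns the
six muscle commands for an observation; `evaluate()`,
`activation_distribution()` and `coactivation_distribution()` quantify
the muscle strategies of trained controllers (they are strongly
all-or-nothing: ~90% of commands below 5% or above 95% activation).

The full experiment grid — every algorithm × force level × many seeds —
runs through `run_grid()` or the CLI:

```sh
Rscript inst/cli/fesreach.R grid --controllers 4 --out grid_out/
```

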