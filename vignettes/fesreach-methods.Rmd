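---
title: "Models and methods behind fesreach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fesreach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fesreach` is a testbed for functional electrical stimulation (FES) control
strategies. It couples a minimal but dynamically honest model of the human
arm in the horizontal plane to goal-conditioned reinforcement-learning
controllers, and measures the controllers the way an FES experimenter
would: fraction of targets acquired, time to target, and the muscle
activation strategies the controllers discover. This vignette documents
the models, the numerical choices, and the places where we had to make a
judgement call.

## The musculoskeletal arm

The arm has two rigid segments (upper arm and forearm-plus-hand) moving on
a frictionless horizontal tabletop, so gravity never enters. Both joints
are pin joints. Six Hill-type actuators drive it: four monoarticular
(anterior deltoid, posterior deltoid, brachialis, triceps short head) and
two biarticular (biceps, triceps long head), each pulling through a
constant signed moment arm $r$ at every joint it crosses.

The state is $(\theta_1, \theta_2, \omega_1, \omega_2, a_{1..6})$: shoulder
and elbow angle, their velocities, and the six muscle activation states.
Each control step (20 ms) performs, in order:

1. **Activation dynamics.** First-order excitation-to-activation lag
   $\dot a = (u - a)/\tau$ with $\tau_{act} = 15$ ms when $u \ge a$ and
   $\tau_{deact} = 50$ ms otherwise, forward-Euler stepped and clipped to
   $[0, 1]$. (With $\tau_{act} < dt$ a full-excitation step saturates in
   one step; the clip makes that exact rather than an overshoot.)
2. **Muscle mechanics.** Muscle-tendon length and velocity follow the
   constant-moment-arm excursion $l_i = l_{ref,i} - r_{1i}\theta_1 -
   r_{2i}\theta_2$. Active force is
   $F_i = s \cdot F_{max,i}\, a_i\, f_L(l_i/l_{opt,i})\, f_V(v_i / (v_{max,i} l_{opt,i}))$
   with $s$ the global force scale, $f_L(x) = \exp(-((x-1)/0.45)^2)$ a
   Gaussian force-length curve, and $f_V$ a Hill hyperbola: 1 at zero
   velocity, 0 at maximal shortening velocity ($v_{max} = 10\,l_{opt}/s$),
   plateauing at 1.4 in lengthening. Forces are clamped nonnegative.
3. **Rigid-body dynamics.** Standard planar two-link equations
   $M(\theta)\dot\omega + C(\theta,\omega) + B\omega = \tau$, with
   $\tau_j = \sum_i r_{ji} F_i$, forward-Euler stepped at the same 20 ms.
4. **Joint limits.** A joint pushed past its limit (shoulder
   $[-10^\circ, 170^\circ]$, elbow $[0^\circ, 160^\circ]$) is clamped to
   the limit with its velocity zeroed — a hard stop.

**Why viscous damping?** We include a small passive joint damping
$B = 0.3$ N·m·s/rad. A frictionless double pendulum under plain forward
Euler at 20 ms gains energy and can blow up under sustained excitation;
passive tissue viscosity is a standard component of limb models and keeps
the integrator honest without sub-stepping. Sub-stepping is available
(`arm_params(substeps = )`) but off by default: a single Euler step per
20 ms control period is the model definition here, not an approximation to
a finer one.

**Anthropometry.** Defaults are Winter-style scalings for an 80 kg,
177 cm adult: $L_1 = 0.329$ m, $m_1 = 2.24$ kg, $m_2 = 1.78$ kg, centres
of mass at 43-44% of segment length, inertias from radius-of-gyration
scaling. The forearm segment length $L_2 = 0.330$ m runs from the elbow to
the *hand grip point*, which is the controlled endpoint — the wrist would
give $\approx 0.26$ m. The grip-point choice is validated by the task
geometry: with targets drawn uniformly from the $[20^\circ, 90^\circ]^2$
joint box, successive target endpoints are $27 \pm 17$ cm apart (mean ±
SD, Monte Carlo), the workspace statistic this task is defined by; the
wrist endpoint gives $23.5 \pm 14.8$ cm.

**Muscle table.** Published parameter sets for this exact six-muscle
reduction are not available, so the default table (`default_muscles()`)
uses physiologically plausible values: $F_{max}$ 700-1200 N, moment arms
2-4 cm with signs set by flexor/extensor role, optimal fiber lengths
0.11-0.15 m referenced so every muscle is at $l_{opt}$ in the middle of
the workspace ($55^\circ, 55^\circ$). Everything is an editable
data frame column, and the YAML config round-trips it, so alternative
tables plug in without code changes.

## The reaching task

A reach gives the controller 1 s (50 steps) to bring the endpoint into a
circular target of radius 7.5 cm and hold it there for 0.1 s
(5 consecutive steps). Goal postures are uniform over
$[20^\circ, 90^\circ]$ per joint. Reaches run back to back: each starts
from the full arm state in which the previous one ended, so targets
sometimes spawn on top of the endpoint — an intentional feature of the
carry-over protocol, and the reason `times_to_target` can be exactly 0.
The very first reach of a run starts at rest at the centre of the spawn
box (the protocol does not define it; rest-at-centre is the least
informative choice).

The observation is $(\theta_1, \theta_2, \omega_1, \omega_2)$ plus the
goal posture. Muscle activations are deliberately hidden: an FES
controller cannot observe the internal state of a stimulated muscle.

The per-step reward is
$r = -0.1 + 1\cdot[\text{in target}] - 0.245\sqrt{\textstyle\sum_i a_i^2}$:
a constant time penalty, a target bonus, and an effort penalty that makes
the redundant muscle system prefer sparse solutions. The target bonus is
granted on *every* in-target step (the one-shot variant is available as
`task_config(reward_mode = "once")`); the per-step form is the standard
sparse-goal convention and is self-consistent under hindsight relabeling.
Episode success requires the completed dwell, so `time_to_target` is
`dt * (terminating step - dwell_steps)` with a hard ceiling of 0.9 s.

## Controllers

DDPG and TD3 are implemented from scratch in base-R matrix algebra (there
is no neural-network dependency): actors and critics are 2×64 ReLU
networks trained with Adam, the actor output squashed to $[0,1]^6$ through
a scaled tanh. TD3 adds twin critics with a min-target, clipped Gaussian
smoothing noise on the target action, and actor/target updates delayed by
a factor 2. Exploration is ε-uniform with ε = 0.3 — 30% of training
actions are drawn uniformly from the action cube, the rest are the
deterministic actor output; evaluation always uses ε = 0.

Hindsight experience replay uses the "future" strategy with $k = 4$: each
stored transition is accompanied by four copies whose goal is replaced by
a posture actually achieved later in the same reach, with reward and
termination recomputed from the success predicate (forward-kinematic
endpoint distance against the target radius). The final transition of a
reach relabels to its own achieved state, guaranteeing at least one
success per stored reach.

Unpublished hyperparameters were fixed to the defaults of the
reinforcement-learning library generation the task was designed around:
$\gamma = 0.98$, $\tau = 0.005$, learning rates $10^{-3}$, batch size 128,
replay capacity $10^6$, policy delay 2, smoothing noise 0.2 clipped at
0.5, one gradient update per environment step after a 1,000-step warmup.
All randomness flows through R's RNG from a single integer seed, so any
run — including the full learning curve — is bitwise reproducible.

**Network inputs are unnormalized**: the raw observation (radians,
rad/s) concatenated with the goal posture. An elementwise input scale is
available (`agent_config(obs_scale = )`) but defaults to ones, and this
choice is load-bearing. With a 0.2 scale on the velocity components —
bringing all inputs to order 1 — *every* variant, HER or not, learns the
task to ~100% success within 30,000 steps, and the HER comparison
degenerates. With raw inputs the picture matches the motivating
phenomenon for hindsight relabeling: at 30,000 steps a DDPG-HER seed
reaches ~90% success while plain DDPG plateaus near the ~10% chance
level produced by targets spawning on the endpoint; TD3 variants learn
with or without HER (plain TD3 also trains successfully in a majority of
cases), with HER speeding convergence. Trained controllers adopt
all-or-nothing muscle commands (~90% of commands below 5% or above 95%).
These are the behaviors the acceptance tests assert at reduced scale,
one seed per algorithm variant.

A consequence worth stating plainly: on this plant the benefit of
hindsight relabeling is regime-dependent. It is decisive exactly where
the critic's learning problem is poorly conditioned; innocuous-looking
input preprocessing can move the task out of that regime entirely.

## Evaluation protocol

`evaluate()` runs 100 consecutive reaches with carry-over states and
ε = 0. An evaluation block starts from the spawn-box centre rather than
inheriting the training state (whether the original protocol carried
state across the training/evaluation boundary is unknowable; starting
clean makes blocks exchangeable). A controller is *successfully trained*
if its final block acquires at least one target. Activation and
coactivation distributions pool the commanded (not the lagged internal)
activations of controllers exceeding 90% success; a muscle counts as
active above 10% command, strictly.

`target_size_sweep()` re-evaluates a frozen controller at radii
7.5 → 0.625 cm. Two modes: `"resimulate"` (fresh rollouts per radius — the
experimental procedure) and `"rescore"` (re-scoring one set of stored
trajectories, which makes the success-nesting property exact and
testable).

## Problem sizes in the test suite

The unit tests run the simulator at full fidelity but train only
micro-runs. The acceptance suite trains one controller per algorithm
variant for 30,000 steps — the point where the HER variants have
converged — rather than the 32 × 100,000-step grid of a full study; the
full grid is one `run_grid()`/CLI call away. The HER-versus-no-HER
comparison at one seed per cell is an ordering check, not an estimate of
the population fraction of trainable controllers.

## What the synthetic setting does not show

Everything here is simulation against one reconstructed plant. Strategy
statistics are especially sensitive to that reconstruction: with this
muscle table (strong maximal forces, small passive damping) trained
controllers can hold posture at near-zero activation, so the modal
number of coactive muscles (>10% command) is 0 here, whereas a plant
requiring sustained antagonist drive would push that mode up toward 3.
The *all-or-nothing* character of the commands is robust; the exact
coactivation count is not. The muscle
table is plausible rather than subject-specific; real FES involves
electrode selectivity, fatigue, spasticity, day-to-day variation and
sensor noise, none of which are modeled. Passing tests demonstrate that
the learning system solves this MIMO, redundant, biarticular reaching
problem from sparse rewards — not that the same hyperparameters would
drive a human arm.
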