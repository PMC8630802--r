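#' Arm model parameters
#'
#' Builds the parameter set for the horizontal-plane two-segment arm. The
#' shoulder is the origin; the upper arm (length `L1`) connects shoulder to
#' elbow and the forearm segment (length `L2`) runs from the elbow to the
#' hand's grip point, which is the controlled endpoint. Both joints are pin
#' joints; motion is confined to the horizontal plane, so gravity plays no
#' role. Defaults are anthropometric values for an 80 kg, 177 cm adult
#' (Winter-style segment scaling), with the endpoint taken at the hand grip
#' rather than the wrist.
#'
#' Segment moments of inertia `I1`, `I2` are taken about each segment's
#' proximal joint. `force_scale` multiplies every muscle's maximal force
#' uniformly; `0.5` emulates the reduced forces of atrophied, electrically
#' stimulated muscle.
#'
#' @param L1,L2 segment lengths (m): shoulder-elbow, elbow-endpoint.
#' @param m1,m2 segment masses (kg).
#' @param c1,c2 centre-of-mass distances from the proximal joint (m).
#' @param I1,I2 segment moments of inertia about the proximal joint (kg m^2).
#' @param joint_limits 2x2 matrix, rows = shoulder/elbow, cols = min/max (rad).
#' @param damping passive viscous joint damping (N m s/rad), length 1 or 2.
#' @param force_scale global multiplier on maximal muscle forces, in (0, 1].
#' @param dt integration/control step (s); the model is updated every 20 ms.
#' @param substeps integer number of Euler sub-steps per control step
#'   (default 1: a single forward-Euler step per 20 ms).
#' @return an object of class `arm_params`.
#' @export
arm_params <- function(L1 = 0.329, L2 = 0.330,
                       m1 = 2.24, m2 = 1.78,
                       c1 = 0.436 * L1, c2 = 0.430 * L2,
                       I1 = m1 * ((0.322 * L1)^2 + c1^2),
                       I2 = m2 * ((0.322 * L2)^2 + c2^2),
                       joint_limits = rbind(shoulder = c(-10, 170),
                                            elbow    = c(0, 160)) * pi / 180,
                       damping = 0.3,
                       force_scale = 1.0,
                       dt = 0.02,
                       substeps = 1L) {
  stopifnot(L1 > 0, L2 > 0, m1 > 0, m2 > 0, I1 > 0, I2 > 0,
            c1 > 0, c2 > 0, dt > 0, substeps >= 1)
  if (!(force_scale > 0 && force_scale <= 1))
    stop("force_scale must be in (0, 1]")
  joint_limits <- matrix(as.numeric(joint_limits), 2, 2,
                         dimnames = list(c("shoulder", "elbow"), c("min", "max")))
  if (any(joint_limits[, 1] >= joint_limits[, 2]))
    stop("joint_limits must satisfy min < max for each joint")
  spawn <- c(20, 90) * pi / 180
  if (any(joint_limits[, 1] >= spawn[1]) || any(joint_limits[, 2] <= spawn[2]))
    stop("the target spawn box [20, 90] deg must lie strictly inside joint_limits")
  p <- list(L1 = L1, L2 = L2, m1 = m1, m2 = m2, c1 = c1, c2 = c2,
            I1 = I1, I2 = I2, joint_limits = joint_limits,
            damping = rep_len(as.numeric(damping), 2L),
            force_scale = force_scale, dt = dt,
            substeps = as.integer(substeps))
  class(p) <- "arm_params"
  p
}

#' Default six-muscle actuator table
#'
#' Hill-type actuator parameters for the six muscles of the planar arm:
#' four monoarticular (anterior deltoid, posterior deltoid, brachialis,
#' triceps short head) and two biarticular (biceps, triceps long head).
#' Moment arms are constant; positive moment arms flex the joint (increase
#' its angle), negative extend it, and a zero moment arm marks a joint the
#' muscle does not cross. `l_ref` is the muscle-tendon length at the
#' reference posture `theta_ref` (workspace centre, 55 deg at both joints),
#' chosen so each muscle sits at its optimal fiber length there.
#'
#' Maximal forces and moment arms are physiologically plausible values in
#' the 500-1500 N and 2-4 cm ranges; activation/deactivation time constants
#' are 15/50 ms and the maximal shortening velocity is 10 optimal fiber
#' lengths per second.
#'
#' @param theta_ref posture (rad) at which every muscle is at optimal length.
#' @return a `data.frame` with one row per muscle and columns `name`,
#'   `Fmax` (N), `l_opt` (m), `r_shoulder`, `r_elbow` (m), `tau_act`,
#'   `tau_deact` (s), `v_max` (l_opt/s) and `l_ref` (m).
#' @export
default_muscles <- function(theta_ref = c(55, 55) * pi / 180) {
  m <- data.frame(
    name       = c("ant_deltoid", "post_deltoid", "brachialis",
                   "triceps_short", "biceps", "triceps_long"),
    Fmax       = c(1200, 1200, 1000, 800, 700, 800),
    l_opt      = c(0.13, 0.13, 0.11, 0.12, 0.15, 0.15),
    r_shoulder = c(0.040, -0.040, 0.000, 0.000, 0.020, -0.020),
    r_elbow    = c(0.000, 0.000, 0.030, -0.025, 0.035, -0.025),
    tau_act    = 0.015,
    tau_deact  = 0.050,
    v_max      = 10,
    stringsAsFactors = FALSE
  )
  m$l_ref <- m$l_opt + m$r_shoulder * theta_ref[1] + m$r_elbow * theta_ref[2]
  validate_muscles(m)
  m
}

validate_muscles <- function(m) {
  need <- c("name", "Fmax", "l_opt", "r_shoulder", "r_elbow",
            "tau_act", "tau_deact", "v_max", "l_ref")
  if (!all(need %in% names(m))) stop("muscle table missing columns: ",
                                     paste(setdiff(need, names(m)), collapse = ", "))
  if (nrow(m) != 6L) stop("exactly 6 muscles are required")
  bi <- m$r_shoulder != 0 & m$r_elbow != 0
  mono <- xor(m$r_shoulder != 0, m$r_elbow != 0)
  if (sum(bi) != 2L || sum(mono) != 4L)
    stop("muscle table must have 4 monoarticular and 2 biarticular muscles")
  stopifnot(all(m$Fmax > 0), all(m$l_opt > 0), all(m$tau_act > 0),
            all(m$tau_deact > 0), all(m$v_max > 0))
  invisible(m)
}

#' Arm state constructor
#'
#' @param theta joint angles (rad), `c(shoulder, elbow)`.
#' @param omega joint angular velocities (rad/s).
#' @param act muscle activation states, 6-vector in \[0, 1\].
#' @return an object of class `arm_state`.
#' @export
arm_state <- function(theta = c(0, 0), omega = c(0, 0), act = rep(0, 6)) {
  stopifnot(length(theta) == 2, length(omega) == 2, length(act) == 6,
            all(is.finite(theta)), all(is.finite(omega)), all(is.finite(act)),
            all(act >= 0), all(act <= 1))
  s <- list(theta = as.numeric(theta), omega = as.numeric(omega),
            act = as.numeric(act))
  class(s) <- "arm_state"
  s
}

#' Forward kinematics of the planar arm
#'
#' Maps joint angles to the Cartesian endpoint. The origin is the shoulder,
#' +x points to anatomical right and +y anterior. The shoulder angle
#' `theta[1]` is measured from the +x axis; the elbow angle `theta[2]` is
#' flexion relative to the upper-arm axis.
#'
#' @param theta 2-vector of joint angles (rad), or an n x 2 matrix.
#' @param params an [arm_params()] object.
#' @return endpoint coordinates (m): a 2-vector, or an n x 2 matrix.
#' @export
forward_kinematics <- function(theta, params) {
  if (is.matrix(theta)) {
    cbind(x = params$L1 * cos(theta[, 1]) + params$L2 * cos(theta[, 1] + theta[, 2]),
          y = params$L1 * sin(theta[, 1]) + params$L2 * sin(theta[, 1] + theta[, 2]))
  } else {
    c(params$L1 * cos(theta[1]) + params$L2 * cos(theta[1] + theta[2]),
      params$L1 * sin(theta[1]) + params$L2 * sin(theta[1] + theta[2]))
  }
}

#' Muscle-tendon lengths and velocities
#'
#' Constant-moment-arm tendon excursion: each muscle's length decreases
#' linearly with the angles of the joints it flexes,
#' `l_i = l_ref_i - r_shoulder_i * theta1 - r_elbow_i * theta2`, and its
#' contraction velocity is the time derivative
#' `v_i = -r_shoulder_i * omega1 - r_elbow_i * omega2` (positive =
#' lengthening). A monoarticular muscle is unaffected by the joint it does
#' not cross.
#'
#' @param state an [arm_state()].
#' @param muscles a muscle table as from [default_muscles()].
#' @return list with numeric 6-vectors `length` (m) and `velocity` (m/s).
#' @export
muscle_kinematics <- function(state, muscles) {
  list(length   = muscles$l_ref - muscles$r_shoulder * state$theta[1] -
                  muscles$r_elbow * state$theta[2],
       velocity = -muscles$r_shoulder * state$omega[1] -
                  muscles$r_elbow * state$omega[2])
}

# Gaussian active force-length curve, peak 1 at optimal length.
force_length <- function(lnorm) exp(-((lnorm - 1) / 0.45)^2)

# Hill force-velocity curve on normalized velocity v / (v_max * l_opt)
# (positive = lengthening). Concentric branch is the classic hyperbola,
# 1 at isometric and 0 at maximal shortening; eccentric branch rises to a
# plateau of 1.4.
force_velocity <- function(vnorm) {
  fv <- numeric(length(vnorm))
  s <- -vnorm                      # normalized shortening speed
  con <- s >= 0
  fv[con] <- pmax(0, (1 - s[con]) / (1 + 4 * s[con]))
  e <- vnorm[!con]                 # lengthening speed
  fv[!con] <- (1.4 * e + 0.04) / (e + 0.04)
  fv
}

#' Hill-type muscle forces
#'
#' Active contractile force of each actuator:
#' `F_i = force_scale * Fmax_i * a_i * f_L(l_i / l_opt_i) * f_V(v_i / (v_max_i l_opt_i))`
#' with a unimodal (Gaussian) force-length curve peaking at the optimal
#' fiber length and a Hill force-velocity curve equal to 1 at zero velocity,
#' falling to 0 at the maximal shortening velocity and plateauing at 1.4
#' for lengthening. Forces are nonnegative: muscles only pull.
#'
#' @inheritParams muscle_kinematics
#' @param params an [arm_params()] object (supplies `force_scale`).
#' @return numeric 6-vector of muscle forces (N).
#' @export
muscle_forces <- function(state, muscles, params) {
  stopifnot(all(state$act >= 0), all(state$act <= 1))
  mk <- muscle_kinematics(state, muscles)
  fl <- force_length(mk$length / muscles$l_opt)
  fv <- force_velocity(mk$velocity / (muscles$v_max * muscles$l_opt))
  pmax(0, params$force_scale * muscles$Fmax * state$act * fl * fv)
}

#' Joint torques from muscle forces
#'
#' Sums each muscle's force times its signed moment arm at each joint:
#' `tau_j = sum_i r_{j,i} F_i`. The sign of the moment arm encodes
#' flexor (positive) versus extensor (negative) action.
#'
#' @param forces nonnegative 6-vector of muscle forces (N).
#' @param muscles a muscle table.
#' @return 2-vector of torques (N m): `c(shoulder, elbow)`.
#' @export
joint_torques <- function(forces, muscles) {
  c(sum(muscles$r_shoulder * forces), sum(muscles$r_elbow * forces))
}

# Mass matrix and Coriolis/centripetal vector of the planar 2-link chain
# (I1, I2 about proximal joints; no gravity in the horizontal plane).
arm_inertia <- function(theta2, p) {
  h <- p$m2 * p$L1 * p$c2 * cos(theta2)
  matrix(c(p$I1 + p$I2 + p$m2 * p$L1^2 + 2 * h,
           p$I2 + h,
           p$I2 + h,
           p$I2), 2, 2)
}

arm_coriolis <- function(theta2, omega, p) {
  h <- p$m2 * p$L1 * p$c2 * sin(theta2)
  c(-h * omega[2]^2 - 2 * h * omega[1] * omega[2],
    h * omega[1]^2)
}

#' Advance the arm one control step
#'
#' One 20 ms forward-Euler step of the full model. In order: (1) first-order
#' activation dynamics `da/dt = (u - a)/tau` with `tau = tau_act` when the
#' excitation exceeds the current activation and `tau_deact` otherwise,
#' Euler-stepped and clipped to \[0, 1\]; (2) rigid-body dynamics
#' `M(theta) domega/dt + C(theta, omega) + B omega = tau_muscle`,
#' Euler-stepped; (3) joint-limit clamp — a joint pushed past its limit is
#' set to the limit with its velocity zeroed, emulating a hard stop.
#' The step is a pure function of its inputs: identical calls agree bitwise.
#'
#' @param state an [arm_state()].
#' @param excitation 6-vector of muscle excitations; values outside \[0, 1\]
#'   are clipped with a warning.
#' @param params an [arm_params()].
#' @param muscles a muscle table.
#' @return the next [arm_state()].
#' @export
arm_step <- function(state, excitation, params, muscles) {
  if (any(!is.finite(state$theta)) || any(!is.finite(state$omega)) ||
      any(!is.finite(state$act)))
    stop("non-finite arm state: numerical blow-up")
  if (any(excitation < 0 | excitation > 1)) {
    warning("excitation outside [0, 1] clipped")
    excitation <- pmin(1, pmax(0, excitation))
  }
  dt <- params$dt / params$substeps
  theta <- state$theta; omega <- state$omega; act <- state$act
  for (k in seq_len(params$substeps)) {
    tau_a <- ifelse(excitation >= act, muscles$tau_act, muscles$tau_deact)
    act <- pmin(1, pmax(0, act + dt * (excitation - act) / tau_a))

    s <- list(theta = theta, omega = omega, act = act)
    forces <- muscle_forces(s, muscles, params)
    tau <- joint_torques(forces, muscles)
    M <- arm_inertia(theta[2], params)
    C <- arm_coriolis(theta[2], omega, params)
    alpha <- solve(M, tau - C - params$damping * omega)

    theta_new <- theta + dt * omega
    omega <- omega + dt * alpha
    theta <- theta_new

    lim <- params$joint_limits
    for (j in 1:2) {
      if (theta[j] < lim[j, 1]) { theta[j] <- lim[j, 1]; omega[j] <- 0 }
      if (theta[j] > lim[j, 2]) { theta[j] <- lim[j, 2]; omega[j] <- 0 }
    }
  }
  if (any(!is.finite(theta)) || any(!is.finite(omega)))
    stop("non-finite arm state after step: numerical blow-up")
  arm_state(theta, omega, act)
}

#' Uniformly rescale maximal muscle forces
#'
#' Returns a copy of the arm parameters with `force_scale` set to
#' `fraction`, scaling every muscle's maximal force uniformly. `1.0` is the
#' able-bodied condition; `0.5` emulates atrophied muscle under electrical
#' stimulation.
#'
#' @param params an [arm_params()].
#' @param fraction new force scale, in (0, 1].
#' @return the modified `arm_params` object.
#' @export
set_force_scale <- function(params, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      !is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be a single number in (0, 1]")
  params$force_scale <- fraction
  params
}
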