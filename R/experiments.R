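#' Experiment grid specification
#'
#' Describes a grid of controller-training runs: which algorithm variants,
#' which muscle-force levels, how many independent controllers per cell and
#' how long to train each. Run seeds are derived deterministically as
#' `base_seed + run index`, so the grid is reproducible and each run is
#' independently seeded.
#'
#' @param algorithms subset of `"DDPG"`, `"DDPG-HER"`, `"TD3"`, `"TD3-HER"`.
#' @param force_levels muscle force scales, subset of `c(1.0, 0.5)` (other
#'   values in (0, 1] are allowed).
#' @param n_controllers controllers trained per (algorithm, force) cell.
#' @param total_steps training steps per controller.
#' @param base_seed integer base seed.
#' @return an object of class `experiment_grid`.
#' @export
experiment_grid <- function(algorithms = c("DDPG", "DDPG-HER", "TD3", "TD3-HER"),
                            force_levels = c(1.0, 0.5),
                            n_controllers = 32L,
                            total_steps = 100000L,
                            base_seed = 1L) {
  known <- c("DDPG", "DDPG-HER", "TD3", "TD3-HER")
  if (!all(algorithms %in% known))
    stop("algorithms must be a subset of ", paste(known, collapse = ", "))
  stopifnot(n_controllers >= 1, total_steps >= 1,
            all(force_levels > 0), all(force_levels <= 1))
  g <- list(algorithms = algorithms, force_levels = force_levels,
            n_controllers = as.integer(n_controllers),
            total_steps = as.integer(total_steps),
            base_seed = as.integer(base_seed))
  class(g) <- "experiment_grid"
  g
}

algo_config <- function(label, seed, ...) {
  base <- strsplit(label, "-")[[1]][1]
  agent_config(algorithm = base, use_her = grepl("-HER$", label),
               seed = seed, ...)
}

#' Run an experiment grid
#'
#' Trains `n_controllers` controllers for every (algorithm, force level)
#' cell of the grid, sequentially. Per-run learning curves (and checkpoints
#' when `out_dir` is given) are written as they complete; an interrupted
#' grid rerun with the same `out_dir` resumes from the existing
#' checkpoints. The summary reports, per cell, the fraction of controllers
#' successfully trained (acquired at least one target in the final
#' evaluation) and the mean final fraction of successful reaches, plus the
#' pooled fractions for HER versus no-HER variants.
#'
#' @param grid an [experiment_grid()].
#' @param out_dir optional output directory for curves, checkpoints and
#'   summary tables.
#' @param params,muscles,task model/task objects shared by all runs (the
#'   force level of each cell overrides `params$force_scale`).
#' @param eval_every,eval_reaches evaluation schedule passed to
#'   [train_controller()].
#' @param keep_controllers return the trained controller objects? (memory
#'   heavy for large grids; default `FALSE` keeps summaries only).
#' @param verbose print progress lines?
#' @param ... extra arguments to [agent_config()] applied to every run.
#' @return list with `runs` (one row per run: algorithm, HER flag, force
#'   level, seed, trained flag, final fraction success, median time to
#'   target), `cells` (per-cell fraction trained and mean success),
#'   `pooled` (HER vs no-HER fraction trained), and optionally
#'   `controllers`.
#' @export
run_grid <- function(grid, out_dir = NULL,
                     params = arm_params(), muscles = default_muscles(),
                     task = task_config(),
                     eval_every = 15000L, eval_reaches = 100L,
                     keep_controllers = FALSE, verbose = FALSE, ...) {
  stopifnot(inherits(grid, "experiment_grid"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  runs <- NULL
  controllers <- list()
  run_idx <- 0L
  for (force in grid$force_levels) {
    for (alg in grid$algorithms) {
      for (i in seq_len(grid$n_controllers)) {
        run_idx <- run_idx + 1L
        seed <- grid$base_seed + run_idx - 1L
        tag <- sprintf("%s_force%03d_seed%d", alg, round(100 * force), seed)
        ckpt <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".rds"))
        ctrl <- NULL
        if (!is.null(ckpt) && file.exists(ckpt)) {
          ctrl <- load_controller(ckpt)
        } else {
          cfg <- algo_config(alg, seed = seed, ...)
          p <- set_force_scale(params, force)
          ctrl <- train_controller(p, muscles, task, cfg,
                                   total_steps = grid$total_steps,
                                   eval_every = eval_every,
                                   eval_reaches = eval_reaches)
          if (!is.null(ckpt)) {
            save_controller(ctrl, ckpt)
            utils::write.csv(ctrl$curve,
                             file.path(out_dir, paste0(tag, "_curve.csv")),
                             row.names = FALSE)
          }
        }
        fin <- ctrl$evals[[length(ctrl$evals)]]
        runs <- rbind(runs, data.frame(
          algorithm = alg, use_her = grepl("-HER$", alg), force = force,
          seed = seed, trained = controller_trained(fin),
          final_fraction_success = fin$fraction_success,
          median_time_to_target = if (length(fin$times_to_target))
            stats::median(fin$times_to_target) else NA_real_))
        if (keep_controllers) controllers[[tag]] <- ctrl
        if (verbose)
          message(sprintf("%s: trained=%s success=%.2f", tag,
                          controller_trained(fin), fin$fraction_success))
      }
    }
  }
  cells <- stats::aggregate(cbind(fraction_trained = trained,
                                  mean_final_success = final_fraction_success)
                            ~ algorithm + force, data = runs, FUN = mean)
  pooled <- stats::aggregate(cbind(fraction_trained = trained)
                             ~ use_her, data = runs, FUN = mean)
  out <- list(runs = runs, cells = cells, pooled = pooled)
  if (keep_controllers) out$controllers <- controllers
  if (!is.null(out_dir)) {
    utils::write.csv(runs, file.path(out_dir, "runs.csv"), row.names = FALSE)
    utils::write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  }
  out
}

#' Write a trajectory log
#'
#' Tabular CSV log of one episode: time (s), joint angles (rad), joint
#' velocities (rad/s), the six commanded activations, and the Cartesian
#' endpoint (m).
#'
#' @param episode an episode record from [evaluate()] (`$episodes[[i]]`).
#' @param path output CSV path.
#' @param dt control step (s).
#' @return the path, invisibly.
#' @export
write_trajectory <- function(episode, path, dt = 0.02) {
  tr <- episode$trajectory
  df <- data.frame(time = dt * seq_len(nrow(tr)), tr[, 1:10, drop = FALSE],
                   x = tr[, "x"], y = tr[, "y"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Generate deterministic test fixtures
#'
#' Produces small canned artifacts used by the unit tests and useful for
#' cross-checking a port: a 50-step episode driven by a scripted open-loop
#' excitation program, a 1,000-goal target sequence with its inter-target
#' distance statistics, and a 2,000-step micro-training transcript. All are
#' plain CSV, reproducible bitwise from the seed.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisible list of the file paths written.
#' @export
make_fixtures <- function(seed = 1L, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  params <- arm_params(); muscles <- default_muscles(); task <- task_config()

  # 1. open-loop episode: ramp the shoulder and elbow flexors, then switch
  set.seed(seed)
  state <- arm_state(theta = c(55, 55) * pi / 180)
  rows <- NULL
  for (t in seq_len(50)) {
    u <- numeric(6)
    u[c(1, 3, 5)] <- min(1, t / 25)            # flexors ramp up
    if (t > 30) u <- rev(u)                    # then extensors take over
    state <- arm_step(state, u, params, muscles)
    rows <- rbind(rows, c(time = t * params$dt, state$theta, state$omega,
                          state$act, forward_kinematics(state$theta, params)))
  }
  colnames(rows) <- c("time", "theta1", "theta2", "omega1", "omega2",
                      paste0("a", 1:6), "x", "y")
  f1 <- file.path(dir, "openloop_episode.csv")
  utils::write.csv(as.data.frame(rows), f1, row.names = FALSE)

  # 2. target sequence and its distance statistics
  set.seed(seed)
  goals <- t(replicate(1000, sample_target(params, task)$theta_goal))
  ep <- forward_kinematics(goals, params)
  d <- sqrt(diff(ep[, 1])^2 + diff(ep[, 2])^2)
  f2 <- file.path(dir, "target_sequence.csv")
  utils::write.csv(data.frame(theta1 = goals[, 1], theta2 = goals[, 2],
                              x = ep[, 1], y = ep[, 2]), f2, row.names = FALSE)
  f3 <- file.path(dir, "target_stats.csv")
  utils::write.csv(data.frame(mean_distance_m = mean(d), sd_distance_m = stats::sd(d)),
                   f3, row.names = FALSE)

  # 3. micro-training transcript
  cfg <- agent_config(algorithm = "TD3", use_her = TRUE, seed = seed,
                      learning_starts = 500L, batch_size = 64L)
  ctrl <- train_controller(params, muscles, task, cfg, total_steps = 2000L,
                           eval_every = 1000L, eval_reaches = 10L)
  f4 <- file.path(dir, "micro_run_curve.csv")
  utils::write.csv(ctrl$curve, f4, row.names = FALSE)

  invisible(list(episode = f1, targets = f2, target_stats = f3, curve = f4))
}
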