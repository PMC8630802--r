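# S3 methods for fitted controllers and related objects.

#' @export
print.fes_controller <- function(x, ...) {
  cfg <- x$config
  cat("Reaching controller for the planar 6-muscle arm\n")
  cat(sprintf("  algorithm: %s%s\n", cfg$algorithm,
              if (cfg$use_her) " + HER" else ""))
  cat(sprintf("  trained for %d steps (%.1f simulated minutes), force scale %.2f\n",
              x$total_steps, x$total_steps * x$params$dt / 60,
              x$params$force_scale))
  fin <- x$evals[[length(x$evals)]]
  cat(sprintf("  final evaluation: %.0f%% of %d reaches successful",
              100 * fin$fraction_success, fin$n_reaches))
  if (length(fin$times_to_target))
    cat(sprintf(", median time to target %.2f s",
                stats::median(fin$times_to_target)))
  cat("\n")
  invisible(x)
}

#' @export
summary.fes_controller <- function(object, ...) {
  fin <- object$evals[[length(object$evals)]]
  s <- list(algorithm = object$config$algorithm,
            use_her = object$config$use_her,
            force_scale = object$params$force_scale,
            total_steps = object$total_steps,
            seed = object$config$seed,
            trained = controller_trained(fin),
            final_fraction_success = fin$fraction_success,
            median_time_to_target = if (length(fin$times_to_target))
              stats::median(fin$times_to_target) else NA_real_,
            curve = object$curve)
  class(s) <- "summary.fes_controller"
  s
}

#' @export
print.summary.fes_controller <- function(x, ...) {
  cat(sprintf("%s%s controller, force scale %.2f, seed %d\n", x$algorithm,
              if (x$use_her) "-HER" else "", x$force_scale, x$seed))
  cat(sprintf("  successfully trained: %s\n", x$trained))
  cat(sprintf("  final fraction success: %.2f\n", x$final_fraction_success))
  if (!is.na(x$median_time_to_target))
    cat(sprintf("  median time to target: %.2f s\n", x$median_time_to_target))
  cat("learning curve:\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Predict muscle activations for an observation
#'
#' Applies the trained (deterministic, exploration-free) policy. `newdata`
#' may be a numeric 6-vector `c(theta1, theta2, omega1, omega2, goal1,
#' goal2)` (radians and rad/s), a matrix with those six columns, or a
#' `data.frame` with columns of those names.
#'
#' @param object a `fes_controller`.
#' @param newdata observations (see Details).
#' @param ... unused.
#' @return a matrix with one row per observation and columns `a1`..`a6`.
#' @export
predict.fes_controller <- function(object, newdata, ...) {
  if (is.data.frame(newdata))
    newdata <- as.matrix(newdata[, c("theta1", "theta2", "omega1", "omega2",
                                     "goal1", "goal2")])
  if (!is.matrix(newdata)) newdata <- matrix(as.numeric(newdata), nrow = 1L)
  stopifnot(ncol(newdata) == 6L)
  A <- actor_forward(object$agent, newdata)
  colnames(A) <- paste0("a", 1:6)
  A
}

#' @export
coef.fes_controller <- function(object, ...) {
  w <- object$agent$actor
  out <- list()
  for (l in seq_along(w$W)) {
    out[[paste0("W", l)]] <- w$W[[l]]
    out[[paste0("b", l)]] <- w$b[[l]]
  }
  out
}

#' Plot the learning curve
#'
#' Two panels against simulated training time: the fraction of successful
#' evaluation reaches, and the median time to target of the successful
#' reaches.
#'
#' @param x a `fes_controller`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fes_controller <- function(x, ...) {
  cv <- x$curve
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(cv$sim_minutes, cv$fraction_success, type = "b",
                 xlab = "simulated training time (min)",
                 ylab = "fraction success", ylim = c(0, 1), ...)
  graphics::plot(cv$sim_minutes, cv$median_time_to_target, type = "b",
                 xlab = "simulated training time (min)",
                 ylab = "median time to target (s)", ylim = c(0, 0.9), ...)
  invisible(x)
}

#' Simulate reaches with a trained controller
#'
#' Rolls out `nsim` consecutive evaluation reaches (exploration 0,
#' carry-over start states) and returns the evaluation summary with full
#' per-step trajectories.
#'
#' @param object a `fes_controller`.
#' @param nsim number of reaches.
#' @param seed optional seed for the target sequence.
#' @param ... unused.
#' @return an `eval_summary`.
#' @export
simulate.fes_controller <- function(object, nsim = 10L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  evaluate(object, n_reaches = nsim)
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("Evaluation block: %d reaches, %.0f%% successful\n",
              x$n_reaches, 100 * x$fraction_success))
  if (length(x$times_to_target))
    cat(sprintf("  time to target: median %.2f s, range [%.2f, %.2f] s\n",
                stats::median(x$times_to_target), min(x$times_to_target),
                max(x$times_to_target)))
  invisible(x)
}

#' @export
print.arm_params <- function(x, ...) {
  cat("Planar two-segment arm parameters\n")
  cat(sprintf("  segments: L1 %.3f m (%.2f kg), L2 %.3f m (%.2f kg)\n",
              x$L1, x$m1, x$L2, x$m2))
  cat(sprintf("  force scale %.2f, dt %.0f ms, damping %.2f N m s/rad\n",
              x$force_scale, 1000 * x$dt, x$damping[1]))
  lim <- round(x$joint_limits * 180 / pi)
  cat(sprintf("  joint limits: shoulder [%d, %d] deg, elbow [%d, %d] deg\n",
              lim[1, 1], lim[1, 2], lim[2, 1], lim[2, 2]))
  invisible(x)
}
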