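#' Solver settings for trajectory integration
#'
#' @param horizon integration horizon in (abstract) evolutionary time units.
#' @param dt spacing of the stored output grid; crossing times are refined
#'   by linear interpolation between grid points.
#' @param rtol,atol relative and absolute solver tolerances passed to
#'   [deSolve::ode()].
#' @param clamp clamp stored states to `[0, 1]` after integration.  The
#'   vector field is tangent to the cube analytically, so clamping only
#'   corrects solver round-off.
#' @return A list of class `solver_settings`.
#' @export
solver_settings <- function(horizon = 50, dt = 0.01,
                            rtol = 1e-8, atol = 1e-10, clamp = TRUE) {
  stopifnot(horizon > 0, dt > 0, rtol > 0, atol > 0)
  structure(list(horizon = horizon, dt = dt, rtol = rtol, atol = atol,
                 clamp = clamp),
            class = "solver_settings")
}

#' Integrate the replicator dynamics
#'
#' Solves the three-dimensional replicator system forward in time from an
#' initial mixed-strategy state.  Corners of the cube are exact fixed
#' points; interior trajectories remain inside the cube up to solver
#' tolerance and are clamped to it on output.
#'
#' @param params a [game_parameters()] object.
#' @param init initial state `(x, y, z)` in `[0, 1]^3`.
#' @param settings a [solver_settings()] list.
#' @return A data frame of class `game_trajectory` with columns `time`,
#'   `x`, `y`, `z`, carrying `params`, `init` and `settings` as attributes.
#' @examples
#' traj <- simulate_game(baseline_parameters(), c(0.2, 0.2, 0.2))
#' tail(traj, 1)
#' @export
simulate_game <- function(params, init = c(0.2, 0.2, 0.2),
                          settings = solver_settings()) {
  params <- game_parameters_from(params)
  init <- as_state(init)
  stopifnot(inherits(settings, "solver_settings"))
  p <- as.list(params)

  rhs <- function(t, s, parms) {
    x <- s[1]; y <- s[2]; z <- s[3]
    G <- p$CH - p$CL - p$We - z * (p$alpha1 - p$alpha2) - y * p$Ws
    J <- p$Cg - p$Rg - z * (p$beta1 - p$beta2) -
      (1 - x) * z * p$Fg - (1 - x) * p$Ws
    D <- p$Cp - p$Rp - p$P + p$P * x
    list(c(x * (x - 1) * G, y * (y - 1) * J, z * (z - 1) * D))
  }

  times <- seq(0, settings$horizon, by = settings$dt)
  if (times[length(times)] < settings$horizon) {
    times <- c(times, settings$horizon)
  }
  sol <- deSolve::ode(y = init, times = times, func = rhs, parms = NULL,
                      rtol = settings$rtol, atol = settings$atol)
  if (attr(sol, "istate")[1] < 0) {
    last <- sol[nrow(sol), ]
    stop("ODE solver failed at t = ", last[1], "; last valid state (",
         paste(signif(last[-1], 6), collapse = ", "), ")", call. = FALSE)
  }
  out <- as.data.frame(unclass(sol))
  names(out) <- c("time", "x", "y", "z")
  overshoot <- max(0, max(out$x, out$y, out$z) - 1, -min(out$x, out$y, out$z))
  if (overshoot > 1e-6) {
    warning("trajectory left the unit cube by ", signif(overshoot, 3),
            " before clamping")
  }
  if (settings$clamp) {
    out[c("x", "y", "z")] <- lapply(out[c("x", "y", "z")],
                                    function(v) pmin(pmax(v, 0), 1))
  }
  attr(out, "params") <- params
  attr(out, "init") <- init
  attr(out, "settings") <- settings
  class(out) <- c("game_trajectory", "data.frame")
  out
}

#' Time of durable convergence to a target state
#'
#' Earliest stored time from which the max-norm distance to `target` stays
#' at or below `eps` for the remainder of the trajectory.
#'
#' @param traj a [simulate_game()] trajectory.
#' @param target the target state, default the all-cooperate corner.
#' @param eps convergence radius in max-norm.
#' @return The convergence time, or `NA_real_` if the trajectory never
#'   settles inside the `eps`-ball.
#' @export
convergence_time <- function(traj, target = c(1, 1, 1), eps = 1e-2) {
  stopifnot(eps > 0)
  target <- as_state(target)
  d <- pmax(abs(traj$x - target[["x"]]),
            abs(traj$y - target[["y"]]),
            abs(traj$z - target[["z"]]))
  # largest distance from each time onward: inside the ball for good?
  suffix_max <- rev(cummax(rev(d)))
  i <- which(suffix_max <= eps)[1]
  if (is.na(i)) NA_real_ else traj$time[i]
}

#' First time a component crosses a level
#'
#' First-passage time of one strategy share across `level`, refined by
#' linear interpolation between the bracketing output points.  Used by the
#' sensitivity sweeps to order convergence speeds; unlike
#' [convergence_time()] it does not require the component to remain above
#' the level afterwards.
#'
#' @param traj a [simulate_game()] trajectory.
#' @param component one of `"x"`, `"y"`, `"z"`.
#' @param level threshold level, default 0.99.
#' @return The interpolated crossing time, or `NA_real_` if never crossed.
#' @export
crossing_time <- function(traj, component = c("x", "y", "z"), level = 0.99) {
  component <- match.arg(component)
  v <- traj[[component]]
  i <- which(v >= level)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(traj$time[1])
  t0 <- traj$time[i - 1]; t1 <- traj$time[i]
  v0 <- v[i - 1]; v1 <- v[i]
  t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}

#' Integrate an ensemble of trajectories
#'
#' Runs [simulate_game()] once per initial condition, preserving order.
#'
#' @param params a [game_parameters()] object.
#' @param inits a matrix with columns `(x, y, z)` (one row per run) or a
#'   list of length-3 states, e.g. from [sample_initial_states()].
#' @param settings a [solver_settings()] list shared by all runs.
#' @return A list of `game_trajectory` objects of class `game_ensemble`.
#' @export
simulate_ensemble <- function(params, inits, settings = solver_settings()) {
  if (is.matrix(inits) || is.data.frame(inits)) {
    inits <- lapply(seq_len(nrow(inits)), function(i) as.numeric(inits[i, ]))
  }
  out <- lapply(inits, function(s) simulate_game(params, s, settings))
  class(out) <- c("game_ensemble", "list")
  out
}

#' Final states of an ensemble
#'
#' @param ensemble a [simulate_ensemble()] result.
#' @return A data frame with one row per run and columns `x`, `y`, `z`.
#' @export
final_states <- function(ensemble) {
  rows <- lapply(ensemble, function(tr) tr[nrow(tr), c("x", "y", "z")])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a trajectory as tidy CSV
#'
#' @param traj a [simulate_game()] trajectory.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj)[c("time", "x", "y", "z")], path,
            row.names = FALSE)
  invisible(path)
}
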