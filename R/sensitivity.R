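#' Specify a one-parameter sweep
#'
#' @param parameter name of the swept parameter (one of the 17).
#' @param values ordered vector of distinct finite values to sweep over.
#' @param track which strategy share's convergence to 1 is timed.
#' @param init shared initial state for all runs.
#' @param settings shared [solver_settings()].
#' @param eps convergence margin: timing measures the first crossing of
#'   `1 - eps` by the tracked component.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter, values, track = c("x", "y", "z"),
                       init = c(0.2, 0.2, 0.2),
                       settings = solver_settings(), eps = 0.01) {
  track <- match.arg(track)
  if (!parameter %in% PARAM_NAMES) {
    stop("unknown parameter '", parameter, "'; expected one of ",
         paste(PARAM_NAMES, collapse = ", "), call. = FALSE)
  }
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("swept values must be finite", call. = FALSE)
  }
  if (anyDuplicated(values)) stop("swept values must be distinct", call. = FALSE)
  stopifnot(eps > 0, eps < 1)
  structure(list(parameter = parameter, values = values, track = track,
                 init = as_state(init), settings = settings, eps = eps),
            class = "sweep_spec")
}

#' Run a one-parameter sensitivity sweep
#'
#' Re-simulates the replicator dynamics once per swept value, holding every
#' other parameter, the initial state and the solver settings fixed, and
#' times the first crossing of `1 - eps` by the tracked strategy share.
#' A swept value that violates a structural parameter invariant (e.g. a
#' `We` making `CH <= CL` impossible is not possible, but a `CL >= CH` is)
#' is recorded as a per-value error rather than aborting the sweep.
#'
#' @param base the base [game_parameters()] set.
#' @param spec a [sweep_spec()].
#' @return A list of class `sweep_result` with elements `spec`,
#'   `trajectories` (named by value; `NULL` where a value errored),
#'   `summary` (data frame: `value`, `convergence_time`, `final_x`,
#'   `final_y`, `final_z`), `errors` (named character vector) and
#'   `base_time`, the same timing under the unswept base parameters.
#' @examples
#' res <- sweep_parameter(baseline_parameters(),
#'                        sweep_spec("We", c(30, 50, 70), track = "x"))
#' res$summary
#' @export
sweep_parameter <- function(base, spec) {
  base <- game_parameters_from(base)
  stopifnot(inherits(spec, "sweep_spec"))

  run_one <- function(v) {
    p <- base
    p[spec$parameter] <- v
    p <- game_parameters_from(p) # revalidate; may error
    simulate_game(p, spec$init, spec$settings)
  }

  trajectories <- setNames(vector("list", length(spec$values)),
                           as.character(spec$values))
  errors <- character(0)
  rows <- list()
  for (i in seq_along(spec$values)) {
    v <- spec$values[i]
    res <- tryCatch(run_one(v), error = function(e) e)
    if (inherits(res, "error")) {
      errors[as.character(v)] <- conditionMessage(res)
      rows[[i]] <- data.frame(value = v, convergence_time = NA_real_,
                              final_x = NA_real_, final_y = NA_real_,
                              final_z = NA_real_)
      next
    }
    trajectories[[i]] <- res
    fin <- res[nrow(res), ]
    rows[[i]] <- data.frame(
      value = v,
      convergence_time = crossing_time(res, spec$track, 1 - spec$eps),
      final_x = fin$x, final_y = fin$y, final_z = fin$z
    )
  }

  base_traj <- simulate_game(base, spec$init, spec$settings)
  structure(
    list(spec = spec,
         trajectories = trajectories,
         summary = do.call(rbind, rows),
         errors = errors,
         base_time = crossing_time(base_traj, spec$track, 1 - spec$eps)),
    class = "sweep_result"
  )
}

#' Built-in sensitivity scenarios
#'
#' The six one-parameter experiments studied in the simulation analysis:
#' operating subsidy `We` in {30, 50, 70} and default fine `Ws` in
#' {40, 80, 120}, both tracking the private share `x`; regulation cost `Cg`
#' in {30, 45, 60} and regulation benefit `Rg` in {20, 40, 60}, tracking
#' the government share `y`; monitoring cost `Cp` in {6, 10, 14} and
#' monitoring reward `Rp` in {11, 15, 19}, tracking the public share `z`.
#' The `Cp`/`Rp` grids are symmetric around the baseline values and keep
#' the reward strictly above the cost (`Cp < Rp`), so the all-cooperate
#' corner remains attracting in `z` throughout.
#'
#' @param base the base [game_parameters()] set.
#' @param init,settings,eps passed to every [sweep_spec()].
#' @return A named list of six `sweep_spec` objects: `we_subsidy`,
#'   `ws_penalty`, `cg_cost`, `rg_benefit`, `cp_cost`, `rp_reward`.
#' @export
figure_scenarios <- function(base = baseline_parameters(),
                             init = c(0.2, 0.2, 0.2),
                             settings = solver_settings(), eps = 0.01) {
  mk <- function(parameter, values, track) {
    sweep_spec(parameter, values, track = track, init = init,
               settings = settings, eps = eps)
  }
  list(
    we_subsidy = mk("We", c(30, 50, 70), "x"),
    ws_penalty = mk("Ws", c(40, 80, 120), "x"),
    cg_cost    = mk("Cg", c(30, 45, 60), "y"),
    rg_benefit = mk("Rg", c(20, 40, 60), "y"),
    cp_cost    = mk("Cp", c(6, 10, 14), "z"),
    rp_reward  = mk("Rp", c(11, 15, 19), "z")
  )
}

#' Ordering verdict for a sweep's convergence times
#'
#' Classifies how the tracked component's convergence time varies across
#' the swept values: `"decreasing"` / `"increasing"` when strictly
#' monotone, `"indistinguishable"` when the total spread is below
#' `indistinct_frac` of the base-parameter convergence time (the curves are
#' practically identical), and `"non-monotone"` otherwise.  An absent
#' convergence time (the component never reached the level) is treated as
#' infinite.
#'
#' @param result a [sweep_parameter()] result with at least two successful
#'   runs.
#' @param indistinct_frac spread fraction below which differences are
#'   declared indistinguishable.
#' @return A character verdict, with the numeric spread fraction attached
#'   as attribute `spread_frac`.
#' @export
monotonicity_report <- function(result, indistinct_frac = 0.05) {
  stopifnot(inherits(result, "sweep_result"))
  times <- result$summary$convergence_time
  ok <- !(as.character(result$summary$value) %in% names(result$errors))
  times <- times[ok]
  if (length(times) < 2) {
    stop("monotonicity requires at least two successful runs", call. = FALSE)
  }
  t_ext <- ifelse(is.na(times), Inf, times)
  spread <- if (all(is.finite(t_ext))) max(t_ext) - min(t_ext) else Inf
  spread_frac <- spread / result$base_time
  verdict <- if (is.finite(spread_frac) && spread_frac < indistinct_frac) {
    "indistinguishable"
  } else if (isTRUE(all(diff(t_ext) < 0))) {
    "decreasing"
  } else if (isTRUE(all(diff(t_ext) > 0))) {
    "increasing"
  } else {
    # ties between never-converging runs land here as well
    "non-monotone"
  }
  structure(verdict, spread_frac = spread_frac)
}

#' Export a sweep as tidy CSV
#'
#' Long format: one row per stored time point per swept value, columns
#' `value`, `time`, `x`, `y`, `z`.
#'
#' @param result a [sweep_parameter()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(result, path) {
  blocks <- Map(function(v, tr) {
    if (is.null(tr)) return(NULL)
    cbind(value = as.numeric(v), as.data.frame(tr)[c("time", "x", "y", "z")])
  }, names(result$trajectories), result$trajectories)
  write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}
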