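#' Plot a trajectory's strategy shares over time
#'
#' Time-series of the three strategy shares, in the style of the
#' simulation figures.  Requires ggplot2.
#'
#' @param traj a [simulate_game()] trajectory.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj) {
  require_ggplot()
  long <- data.frame(
    time = rep(traj$time, 3),
    share = c(traj$x, traj$y, traj$z),
    player = rep(c("private (x)", "government (y)", "public (z)"),
                 each = nrow(traj))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = time, y = share, colour = player)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "evolutionary time", y = "strategy share",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the tracked component of a sensitivity sweep
#'
#' One curve per swept value, tracking the component the sweep times.
#'
#' @param result a [sweep_parameter()] result.
#' @return A ggplot object.
#' @export
plot_sweep <- function(result) {
  require_ggplot()
  spec <- result$spec
  blocks <- Map(function(v, tr) {
    if (is.null(tr)) return(NULL)
    data.frame(value = v, time = tr$time, share = tr[[spec$track]])
  }, names(result$trajectories), result$trajectories)
  long <- do.call(rbind, blocks)
  ggplot2::ggplot(long, ggplot2::aes(x = time, y = share, colour = factor(value))) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "evolutionary time",
                  y = paste0("strategy share ", spec$track),
                  colour = spec$parameter) +
    ggplot2::theme_minimal()
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
}

save_plot <- function(p, path, width = 7, height = 4) {
  require_ggplot()
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}

utils::globalVariables(c("time", "share", "player", "value"))
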