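#' Baseline parameter assignment
#'
#' The standard simulation assignment used throughout the stability and
#' sensitivity analyses: `Cp = 10`, `Rp = 15`, `beta1 = 30`, `beta2 = 5`,
#' `Cg = 30`, `Rg = 20`, `alpha1 = 20`, `alpha2 = 10`, `CH = 70`,
#' `CL = 30`, `We = 30`, `Ws = 80`, `Fg = 100`, `P = 300`.  It satisfies
#' all three stability conditions of the all-cooperate corner with margins
#' (-5, -15, -80).
#'
#' `Mi`, `Fi` and `R1` have no assigned values in this scheme because they
#' cancel from every payoff difference and so never affect the dynamics;
#' the defaults here are arbitrary positive placeholders used only for
#' displaying the payoff table, and are recorded in the `"unassigned"`
#' attribute.
#'
#' @param Mi,Fi,R1 placeholder values for the three nuisance parameters.
#' @return A [game_parameters()] object.
#' @examples
#' baseline_parameters()
#' @export
baseline_parameters <- function(Mi = 100, Fi = 100, R1 = 50) {
  p <- game_parameters(
    Mi = Mi, CH = 70, CL = 30, We = 30, Ws = 80,
    alpha1 = 20, alpha2 = 10,
    Fi = Fi, Rg = 20, Cg = 30, beta1 = 30, beta2 = 5,
    Rp = 15, Fg = 100, Cp = 10, R1 = R1, P = 300
  )
  attr(p, "unassigned") <- c("Mi", "Fi", "R1")
  p
}

#' Sample a random parameter regime
#'
#' Draws each parameter independently and uniformly from its range
#' (default `[0.5, 2]` times the baseline value, which keeps draws in the
#' baseline's order of magnitude), then rejection-samples until the
#' requested regime's constraints hold:
#' \describe{
#'   \item{`unconstrained`}{only the structural invariants `CH > CL`,
#'     `alpha1 > alpha2`, `beta1 > beta2`.}
#'   \item{`ess_stable`}{additionally all three stability conditions of
#'     the all-cooperate corner (see [ess_conditions()]), so that corner is
#'     an ESS by construction.}
#'   \item{`ess_violated`}{the condition named by `violate` is reversed
#'     while the other two still hold, so exactly the intended eigenvalue
#'     of the all-cooperate corner is positive.}
#' }
#'
#' @param regime sampling regime, see Details.
#' @param violate for `regime = "ess_violated"`: which player's stability
#'   condition to break (`"public"` is `Cp - Rp`, `"government"` is
#'   `beta2 - beta1 + Cg - Rg`, `"private"` is
#'   `alpha2 - alpha1 + CH - CL - We - Ws`).
#' @param seed integer seed making the draw reproducible; `NULL` uses the
#'   current RNG stream.
#' @param ranges optional named list of `c(lower, upper)` ranges
#'   overriding the defaults for individual parameters.
#' @param max_tries rejection budget.
#' @return A [game_parameters()] object satisfying the regime constraints.
#' @examples
#' p <- sample_parameters("ess_stable", seed = 1)
#' attr(classify_all(p), "ess")
#' @export
sample_parameters <- function(regime = c("unconstrained", "ess_stable",
                                         "ess_violated"),
                              violate = c("public", "government", "private"),
                              seed = NULL, ranges = NULL, max_tries = 10000) {
  regime <- match.arg(regime)
  violate <- match.arg(violate)
  base <- baseline_parameters()

  lo <- 0.5 * as.numeric(base)
  hi <- 2.0 * as.numeric(base)
  names(lo) <- names(hi) <- PARAM_NAMES
  for (nm in names(ranges)) {
    if (!nm %in% PARAM_NAMES) {
      stop("unknown parameter in ranges: ", nm, call. = FALSE)
    }
    lo[nm] <- ranges[[nm]][1]
    hi[nm] <- ranges[[nm]][2]
  }

  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      draw <- setNames(runif(length(PARAM_NAMES), lo, hi), PARAM_NAMES)
      if (draw["CH"] <= draw["CL"]) next
      if (draw["alpha1"] <= draw["alpha2"]) next
      if (draw["beta1"] <= draw["beta2"]) next
      p <- do.call(game_parameters, as.list(draw))
      margins <- setNames(ess_conditions(p)$value,
                          c("public", "government", "private"))
      ok <- switch(regime,
        unconstrained = TRUE,
        ess_stable = all(margins < 0),
        ess_violated = margins[violate] > 0 &&
          all(margins[setdiff(names(margins), violate)] < 0)
      )
      if (ok) return(p)
    }
    stop("rejection budget (", max_tries, ") exhausted sampling regime '",
         regime,
         if (regime == "ess_violated") paste0("' violating '", violate) else "",
         "'", call. = FALSE)
  })
}

#' Sample random interior initial states
#'
#' Draws `n` states uniformly on `[margin, 1 - margin]^3`.
#'
#' @param n number of states (may be 0).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param margin distance kept from the cube faces, in `(0, 0.5)`.
#' @return An `n` x 3 numeric matrix with columns `x`, `y`, `z`.
#' @examples
#' sample_initial_states(3, seed = 1)
#' @export
sample_initial_states <- function(n, seed = NULL, margin = 0.1) {
  stopifnot(n >= 0)
  if (margin <= 0 || margin >= 0.5) {
    stop("margin must lie strictly between 0 and 0.5", call. = FALSE)
  }
  with_seed(seed, {
    m <- matrix(runif(3 * n, margin, 1 - margin), ncol = 3)
    colnames(m) <- c("x", "y", "z")
    m
  })
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
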