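#' Construct a validated set of game parameters
#'
#' The tripartite game is parameterised by 17 non-negative scalars describing
#' the payoffs, costs and reputation effects of the three players: the private
#' operator of a public-private partnership (PPP) facility, the government
#' regulator, and the monitoring public.  All quantities live on one common
#' utility scale (currency and reputation levels are added freely in the
#' payoff table).
#'
#' @param Mi minimum private-sector benefit from user fees (does not affect
#'   the dynamics; it cancels from every payoff difference).
#' @param CH cost of providing a high-quality service; must exceed `CL`.
#' @param CL cost of providing a low-quality service.
#' @param We operating subsidy paid by the government for high-quality
#'   provision.
#' @param Ws fine levied on the private sector when a default (low-quality
#'   provision) is detected under supervision.
#' @param alpha1,alpha2 reputation granted to the private sector by a
#'   monitoring public under high/low quality; `alpha1 > alpha2`.
#' @param Fi government fixed income (cancels from the dynamics).
#' @param Rg extra benefit the government earns from active regulation.
#' @param Cg cost of active regulation.
#' @param beta1,beta2 reputation granted to the government by a monitoring
#'   public when it does/does not regulate; `beta1 > beta2`.
#' @param Rp reward paid by the government to a monitoring public.
#' @param Fg penalty on a non-regulating government when a default is exposed
#'   by the public.
#' @param Cp cost of public monitoring.
#' @param R1 damage to the public from a low-quality service (cancels from
#'   the dynamics).
#' @param P compensation to the public for reporting damage.
#'
#' @return An object of class `game_parameters`: a named numeric vector of
#'   length 17 in canonical order.
#' @seealso [baseline_parameters()] for the standard simulation assignment,
#'   [read_parameters()] / [write_parameters()] for config-file I/O.
#' @examples
#' p <- baseline_parameters()
#' p["We"] <- 50
#' game_parameters_from(p) # revalidate after editing
#' @export
game_parameters <- function(Mi, CH, CL, We, Ws, alpha1, alpha2,
                            Fi, Rg, Cg, beta1, beta2,
                            Rp, Fg, Cp, R1, P) {
  values <- c(
    Mi = Mi, CH = CH, CL = CL, We = We, Ws = Ws,
    alpha1 = alpha1, alpha2 = alpha2,
    Fi = Fi, Rg = Rg, Cg = Cg, beta1 = beta1, beta2 = beta2,
    Rp = Rp, Fg = Fg, Cp = Cp, R1 = R1, P = P
  )
  validate_game_parameters(values)
  structure(as.numeric(values), names = PARAM_NAMES, class = "game_parameters")
}

#' Coerce a named vector or list to validated game parameters
#'
#' @param x a named numeric vector or list containing all 17 parameters.
#' @return A `game_parameters` object.
#' @export
game_parameters_from <- function(x) {
  x <- unlist(x)
  missing <- setdiff(PARAM_NAMES, names(x))
  if (length(missing) > 0) {
    stop("missing game parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  do.call(game_parameters, as.list(x[PARAM_NAMES]))
}

validate_game_parameters <- function(values) {
  values <- unlist(values)[PARAM_NAMES]
  if (anyNA(values) || any(!is.finite(values))) {
    stop("all game parameters must be finite numbers", call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- PARAM_NAMES[values < 0]
    stop("game parameters must be non-negative; violated by: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (values["CH"] <= values["CL"]) {
    stop("parameter invariant violated: CH > CL is required", call. = FALSE)
  }
  if (values["alpha1"] <= values["alpha2"]) {
    stop("parameter invariant violated: alpha1 > alpha2 is required",
         call. = FALSE)
  }
  if (values["beta1"] <= values["beta2"]) {
    stop("parameter invariant violated: beta1 > beta2 is required",
         call. = FALSE)
  }
  invisible(values)
}

#' @export
print.game_parameters <- function(x, ...) {
  cat("Tripartite PPP game parameters:\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Check the stability conditions for the all-cooperate equilibrium
#'
#' The corner (1, 1, 1) -- high-quality provision, active regulation, active
#' monitoring -- is an evolutionary stable strategy exactly when its three
#' Jacobian eigenvalues are negative: `Cp - Rp < 0`,
#' `beta2 - beta1 + Cg - Rg < 0` and
#' `alpha2 - alpha1 + CH - CL - We - Ws < 0`.  This advisory check reports
#' each margin without enforcing it, since parameter sweeps may legitimately
#' cross the boundaries.
#'
#' @param params a [game_parameters()] object.
#' @return A data frame with one row per condition: `player`, the eigenvalue
#'   `value` (negative means satisfied) and logical `satisfied`.
#' @examples
#' ess_conditions(baseline_parameters())
#' @export
ess_conditions <- function(params) {
  params <- game_parameters_from(params)
  p <- as.list(params)
  value <- c(
    public     = p$Cp - p$Rp,
    government = p$beta2 - p$beta1 + p$Cg - p$Rg,
    private    = p$alpha2 - p$alpha1 + p$CH - p$CL - p$We - p$Ws
  )
  data.frame(
    player = names(value),
    condition = c("Cp - Rp < 0",
                  "beta2 - beta1 + Cg - Rg < 0",
                  "alpha2 - alpha1 + CH - CL - We - Ws < 0"),
    value = as.numeric(value),
    satisfied = as.numeric(value) < 0,
    row.names = NULL
  )
}

#' Read game parameters from a YAML or JSON config file
#'
#' The file must contain a flat mapping with exactly the canonical parameter
#' keys (`Mi`, `CH`, `CL`, `We`, `Ws`, `alpha1`, `alpha2`, `Fi`, `Rg`, `Cg`,
#' `beta1`, `beta2`, `Rp`, `Fg`, `Cp`, `R1`, `P`).  Extra keys are ignored
#' with a warning.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `game_parameters` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  values <- switch(file_format(path),
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE)
  )
  extra <- setdiff(names(values), PARAM_NAMES)
  if (length(extra) > 0) {
    warning("ignoring unknown parameter keys: ", paste(extra, collapse = ", "))
  }
  game_parameters_from(values[intersect(names(values), PARAM_NAMES)])
}

#' Write game parameters to a YAML or JSON config file
#'
#' @param params a [game_parameters()] object.
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  params <- game_parameters_from(params)
  values <- as.list(setNames(as.numeric(params), names(params)))
  switch(file_format(path),
    yaml = yaml::write_yaml(values, path),
    json = jsonlite::write_json(values, path, auto_unbox = TRUE, digits = NA)
  )
  invisible(path)
}

file_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return("yaml")
  if (ext == "json") return("json")
  stop("unsupported config format '", ext, "'; use .yaml, .yml or .json",
       call. = FALSE)
}

#' Construct a strategy state
#'
#' The population state of the game: `x` is the share of private operators
#' providing high-quality service, `y` the share of government agencies
#' actively regulating, and `z` the share of the public actively monitoring.
#'
#' @param x,y,z probabilities in `[0, 1]`.
#' @return A named numeric vector `c(x, y, z)` of class `strategy_state`.
#' @export
strategy_state <- function(x, y, z) {
  s <- c(x = x, y = y, z = z)
  validate_strategy_state(s)
  structure(as.numeric(s), names = c("x", "y", "z"), class = "strategy_state")
}

validate_strategy_state <- function(s, tol = 1e-12) {
  s <- unlist(s)
  if (length(s) != 3 || anyNA(s) || any(!is.finite(s))) {
    stop("a strategy state must be three finite numbers (x, y, z)",
         call. = FALSE)
  }
  if (any(s < -tol) || any(s > 1 + tol)) {
    stop("strategy shares must lie in [0, 1]; got (",
         paste(signif(s, 6), collapse = ", "), ")", call. = FALSE)
  }
  invisible(s)
}

as_state <- function(s) {
  s <- unlist(s)
  validate_strategy_state(s)
  setNames(pmin(pmax(as.numeric(s), 0), 1), c("x", "y", "z"))
}
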