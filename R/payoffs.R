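#' Build the 2x2x2 payoff table
#'
#' Enumerates the eight pure-strategy outcomes of the game -- the private
#' sector honours the contract or defaults, the government supervises or not,
#' the public participates in monitoring or not -- and the resulting payoff
#' triple (private, government, public).  Reputation terms (`alpha1`,
#' `alpha2`, `beta1`, `beta2`) accrue only when the public participates; the
#' fine `Ws` moves from operator to government only in
#' violation-under-supervision outcomes; the exposure penalty `Fg` hits a
#' non-supervising government only when a violation is reported by a
#' participating public.
#'
#' @param params a [game_parameters()] object.
#' @return A data frame of class `payoff_table` with eight rows and columns
#'   `no_violation`, `supervises`, `participates` (logicals) and `private`,
#'   `government`, `public` (payoffs).
#' @examples
#' build_payoff_table(baseline_parameters())
#' @export
build_payoff_table <- function(params) {
  params <- game_parameters_from(params)
  p <- as.list(params)

  grid <- expand.grid(
    participates = c(TRUE, FALSE),
    supervises = c(TRUE, FALSE),
    no_violation = c(TRUE, FALSE)
  )[, c("no_violation", "supervises", "participates")]

  cell <- function(nv, sup, part) {
    if (nv) {
      private <- p$Mi + p$We - p$CH + if (part) p$alpha1 else 0
      government <- if (sup && part) {
        p$Fi + p$Rg + p$beta1 - p$Cg - p$Rp
      } else if (sup) {
        p$Fi + p$Rg - p$Cg
      } else if (part) {
        p$Fi + p$beta2 - p$Rp
      } else {
        p$Fi
      }
      public <- if (part) p$Rp - p$Cp else 0
    } else {
      private <- p$Mi - p$CL +
        (if (part) p$alpha2 else 0) - (if (sup) p$Ws else 0)
      government <- if (sup && part) {
        p$Fi + p$Rg + p$Ws + p$beta1 - p$Cg - p$Rp
      } else if (sup) {
        p$Fi + p$Rg + p$Ws - p$Cg
      } else if (part) {
        p$Fi + p$beta2 - p$Rp - p$Fg
      } else {
        p$Fi
      }
      public <- if (part) p$Rp - p$Cp - p$R1 + p$P else -p$R1
    }
    c(private = private, government = government, public = public)
  }

  payoffs <- t(mapply(cell, grid$no_violation, grid$supervises,
                      grid$participates))
  out <- cbind(grid, as.data.frame(payoffs))
  rownames(out) <- NULL
  class(out) <- c("payoff_table", "data.frame")
  out
}

table_cell <- function(table, no_violation, supervises, participates) {
  row <- table[table$no_violation == no_violation &
                 table$supervises == supervises &
                 table$participates == participates, ]
  c(private = row$private, government = row$government, public = row$public)
}

#' Expected payoffs of the private sector
#'
#' Given the opponents' mixed strategies, returns the expected payoff of
#' always providing high quality (`Y11`), of always defaulting (`Y12`), and
#' the population mean `Y1_mean = x Y11 + (1 - x) Y12`.
#'
#' @param params a [game_parameters()] object.
#' @param state a strategy state `(x, y, z)`.
#' @return A named list with elements `Y11`, `Y12`, `Y1_mean`.
#' @export
expected_private_payoffs <- function(params, state) {
  params <- game_parameters_from(params)
  s <- as_state(state)
  p <- as.list(params)
  y <- s["y"]; z <- s["z"]
  Y11 <- y * z * (p$Mi + p$We + p$alpha1 - p$CH) +
    (1 - y) * z * (p$Mi + p$We + p$alpha1 - p$CH) +
    y * (1 - z) * (p$Mi + p$We - p$CH) +
    (1 - y) * (1 - z) * (p$Mi + p$We - p$CH)
  Y12 <- y * z * (p$Mi + p$alpha2 - p$CL - p$Ws) +
    (1 - y) * z * (p$Mi + p$alpha2 - p$CL) +
    y * (1 - z) * (p$Mi - p$CL - p$Ws) +
    (1 - y) * (1 - z) * (p$Mi - p$CL)
  list(Y11 = unname(Y11), Y12 = unname(Y12),
       Y1_mean = unname(s["x"] * Y11 + (1 - s["x"]) * Y12))
}

#' Expected payoffs of the government
#'
#' Expected payoff of always regulating (`Y21`), of never regulating
#' (`Y22`), and the mean `Y2_mean = y Y21 + (1 - y) Y22`.
#'
#' @inheritParams expected_private_payoffs
#' @return A named list with elements `Y21`, `Y22`, `Y2_mean`.
#' @export
expected_government_payoffs <- function(params, state) {
  params <- game_parameters_from(params)
  s <- as_state(state)
  p <- as.list(params)
  x <- s["x"]; z <- s["z"]
  Y21 <- x * z * (p$Fi + p$Rg + p$beta1 - p$Cg - p$Rp) +
    x * (1 - z) * (p$Fi + p$Rg - p$Cg) +
    (1 - x) * z * (p$Fi + p$Rg + p$Ws + p$beta1 - p$Cg - p$Rp) +
    (1 - x) * (1 - z) * (p$Fi + p$Rg + p$Ws - p$Cg)
  Y22 <- x * z * (p$Fi + p$beta2 - p$Rp) +
    x * (1 - z) * p$Fi +
    (1 - x) * z * (p$Fi + p$beta2 - p$Rp - p$Fg) +
    (1 - x) * (1 - z) * p$Fi
  list(Y21 = unname(Y21), Y22 = unname(Y22),
       Y2_mean = unname(s["y"] * Y21 + (1 - s["y"]) * Y22))
}

#' Expected payoffs of the public
#'
#' Expected payoff of monitoring (`Y31`), of not monitoring (`Y32`), and the
#' mean `Y3_mean = z Y31 + (1 - z) Y32`.
#'
#' @inheritParams expected_private_payoffs
#' @return A named list with elements `Y31`, `Y32`, `Y3_mean`.
#' @export
expected_public_payoffs <- function(params, state) {
  params <- game_parameters_from(params)
  s <- as_state(state)
  p <- as.list(params)
  x <- s["x"]; y <- s["y"]
  Y31 <- x * y * (p$Rp - p$Cp) + x * (1 - y) * (p$Rp - p$Cp) +
    (1 - x) * y * (p$Rp - p$Cp - p$R1 + p$P) +
    (1 - x) * (1 - y) * (p$Rp - p$Cp - p$R1 + p$P)
  Y32 <- (1 - x) * y * (-p$R1) + (1 - x) * (1 - y) * (-p$R1)
  list(Y31 = unname(Y31), Y32 = unname(Y32),
       Y3_mean = unname(s["z"] * Y31 + (1 - s["z"]) * Y32))
}

#' Switching functions of the three populations
#'
#' The bracketed payoff-difference terms whose signs steer each population:
#' \deqn{G(y, z) = CH - CL - We - z(\alpha_1 - \alpha_2) - y Ws}
#' \deqn{J(x, z) = Cg - Rg - z(\beta_1 - \beta_2) - (1 - x) z Fg - (1 - x) Ws}
#' \deqn{D(x) = Cp - Rp - P + P x}
#' On the open interval, `G < 0` drives `x` upward, `J < 0` drives `y`
#' upward, and `D < 0` drives `z` upward.
#'
#' The expressions are affine in each mixture and are evaluated as written,
#' without clamping the state to the cube: threshold analysis evaluates
#' them at critical mixtures (`y*`, `z*`, `x*`) that may legitimately fall
#' outside `[0, 1]`.
#'
#' @inheritParams expected_private_payoffs
#' @return A named numeric vector `c(G, J, D)`.
#' @export
switching_functions <- function(params, state) {
  params <- game_parameters_from(params)
  s <- setNames(as.numeric(unlist(state)), c("x", "y", "z"))
  if (length(s) != 3 || any(!is.finite(s))) {
    stop("state must be three finite numbers (x, y, z)", call. = FALSE)
  }
  p <- as.list(params)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]
  c(
    G = p$CH - p$CL - p$We - z * (p$alpha1 - p$alpha2) - y * p$Ws,
    J = p$Cg - p$Rg - z * (p$beta1 - p$beta2) -
      (1 - x) * z * p$Fg - (1 - x) * p$Ws,
    D = p$Cp - p$Rp - p$P + p$P * x
  )
}

#' Replicator rates of the tripartite game (closed form)
#'
#' The replicator system
#' \deqn{dx/dt = x(x - 1) G(y, z), \quad
#'       dy/dt = y(y - 1) J(x, z), \quad
#'       dz/dt = z(z - 1) D(x),}
#' with the switching functions of [switching_functions()].  Every corner of
#' the unit cube is a fixed point.
#'
#' @inheritParams expected_private_payoffs
#' @return A named numeric vector `c(dx, dy, dz)`.
#' @seealso [replicator_rates_from_table()] for the independent
#'   payoff-table route.
#' @export
replicator_rates <- function(params, state) {
  s <- as_state(state)
  g <- switching_functions(params, state)
  c(
    dx = s[["x"]] * (s[["x"]] - 1) * g[["G"]],
    dy = s[["y"]] * (s[["y"]] - 1) * g[["J"]],
    dz = s[["z"]] * (s[["z"]] - 1) * g[["D"]]
  )
}

#' Replicator rates derived from the payoff table
#'
#' Independent route to the replicator rates: each group's
#' strategy-conditional expected payoff is obtained by summing payoff-table
#' cells weighted by the other two groups' mixed strategies, and the rate is
#' `share * (own-strategy payoff - group mean)`.  Serves as the consistency
#' check between the payoff table and the closed-form rate equations.
#'
#' @inheritParams expected_private_payoffs
#' @return A named numeric vector `c(dx, dy, dz)`.
#' @export
replicator_rates_from_table <- function(params, state) {
  params <- game_parameters_from(params)
  s <- as_state(state)
  tab <- build_payoff_table(params)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]

  # expected payoff to `player` of playing `own` (TRUE arm of its move),
  # averaging the other two players' moves under the mixed strategies
  expect_for <- function(player, move, own) {
    total <- 0
    for (i in seq_len(nrow(tab))) {
      row <- tab[i, ]
      if (row[[move]] != own) next
      w <- 1
      if (move != "no_violation") {
        w <- w * if (row$no_violation) x else 1 - x
      }
      if (move != "supervises") {
        w <- w * if (row$supervises) y else 1 - y
      }
      if (move != "participates") {
        w <- w * if (row$participates) z else 1 - z
      }
      total <- total + w * row[[player]]
    }
    total
  }

  rate <- function(share, player, move) {
    own <- expect_for(player, move, TRUE)
    alt <- expect_for(player, move, FALSE)
    mean_payoff <- share * own + (1 - share) * alt
    share * (own - mean_payoff)
  }

  c(
    dx = rate(x, "private", "no_violation"),
    dy = rate(y, "government", "supervises"),
    dz = rate(z, "public", "participates")
  )
}

#' Critical thresholds of the opposing mixtures
#'
#' The mixture levels at which each switching function vanishes:
#' `y* = [CH - CL - We - z(alpha1 - alpha2)] / Ws` (private sector
#' indifferent), `z* = [Rg - Cg + (1 - x) Ws] / [(x - 1) Fg - (beta1 -
#' beta2)]` (government indifferent) and `x* = (P + Rp - Cp) / P` (public
#' indifferent).  Values are returned unclipped: a threshold outside
#' `[0, 1]` means the corresponding population drifts in one direction over
#' the whole feasible range.
#'
#' @inheritParams expected_private_payoffs
#' @return A data frame with rows `y_star`, `z_star`, `x_star` and columns
#'   `value`, `finite`, `in_range`.
#' @examples
#' critical_thresholds(baseline_parameters(), strategy_state(1, 0, 0))
#' @export
critical_thresholds <- function(params, state) {
  params <- game_parameters_from(params)
  s <- as_state(state)
  p <- as.list(params)
  x <- s[["x"]]; z <- s[["z"]]

  y_star <- if (p$Ws > 0) {
    (p$CH - p$CL - p$We - z * (p$alpha1 - p$alpha2)) / p$Ws
  } else {
    NA_real_
  }
  z_den <- (x - 1) * p$Fg - (p$beta1 - p$beta2)
  z_star <- if (z_den != 0) {
    (p$Rg - p$Cg + (1 - x) * p$Ws) / z_den
  } else {
    NA_real_
  }
  x_star <- if (p$P > 0) (p$P + p$Rp - p$Cp) / p$P else NA_real_

  value <- c(y_star = y_star, z_star = z_star, x_star = x_star)
  data.frame(
    threshold = names(value),
    value = as.numeric(value),
    finite = is.finite(value),
    in_range = is.finite(value) & value >= 0 & value <= 1,
    row.names = NULL
  )
}
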