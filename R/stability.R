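#' Jacobian of the replicator system
#'
#' Evaluates the 3x3 Jacobian of the replicator rates with respect to
#' `(x, y, z)`.  The diagonal is `(2x - 1) G`, `(2y - 1) J`, `(2z - 1) D`;
#' the off-diagonal prefactors `x(x - 1)`, `y(y - 1)`, `z(z - 1)` vanish at
#' every cube corner, making the matrix triangular there, so the corner
#' eigenvalues are the diagonal entries.  The public's rate does not depend
#' on `y`, hence entry (3, 2) is identically zero.
#'
#' @inheritParams expected_private_payoffs
#' @return A 3x3 numeric matrix with dimnames `c("x", "y", "z")`.
#' @export
replicator_jacobian <- function(params, state) {
  params <- game_parameters_from(params)
  s <- as_state(state)
  p <- as.list(params)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]
  g <- switching_functions(params, s)

  m <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  m[1, 1] <- (2 * x - 1) * g[["G"]]
  m[1, 2] <- -x * (x - 1) * p$Ws
  m[1, 3] <- -x * (x - 1) * (p$alpha1 - p$alpha2)
  m[2, 1] <- y * (y - 1) * (z * p$Fg + p$Ws)
  m[2, 2] <- (2 * y - 1) * g[["J"]]
  m[2, 3] <- y * (y - 1) * (-(p$beta1 - p$beta2) - (1 - x) * p$Fg)
  m[3, 1] <- z * (z - 1) * p$P
  m[3, 2] <- 0
  m[3, 3] <- (2 * z - 1) * g[["D"]]
  m
}

#' The eight pure-strategy equilibria
#'
#' Corner points of the unit cube, the fixed points the stability analysis
#' classifies, in the conventional order E1(0,0,0), E2(1,0,0), E3(0,1,0),
#' E4(0,0,1), E5(1,1,0), E6(1,0,1), E7(0,1,1), E8(1,1,1).
#'
#' @return An 8x3 numeric matrix with rownames `E1`..`E8` and colnames
#'   `x`, `y`, `z`.
#' @export
pure_equilibria <- function() {
  m <- rbind(
    E1 = c(0, 0, 0), E2 = c(1, 0, 0), E3 = c(0, 1, 0), E4 = c(0, 0, 1),
    E5 = c(1, 1, 0), E6 = c(1, 0, 1), E7 = c(0, 1, 1), E8 = c(1, 1, 1)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

# Symbolic corner eigenvalues.  Each row of the published classification
# table lists the three eigenvalues in a row-specific order; `component`
# records which state direction each printed expression belongs to.
CORNER_EIGEN <- list(
  E1 = list(exprs = c("CL - CH + We", "P - Cp + Rp", "Rg - Cg + Ws"),
            component = c("x", "z", "y")),
  E2 = list(exprs = c("Rg - Cg", "Rp - Cp", "CH - CL - We"),
            component = c("y", "z", "x")),
  E3 = list(exprs = c("Cg - Rg - Ws", "P - Cp + Rp", "CL - CH + We + Ws"),
            component = c("y", "z", "x")),
  E4 = list(exprs = c("Cp - P - Rp", "alpha1 - alpha2 - CH + CL + We",
                      "beta1 - beta2 - Cg + Fg + Rg + Ws"),
            component = c("z", "x", "y")),
  E5 = list(exprs = c("Cg - Rg", "Rp - Cp", "CH - CL - We - Ws"),
            component = c("y", "z", "x")),
  E6 = list(exprs = c("Cp - Rp", "beta1 - beta2 - Cg + Rg",
                      "alpha2 - alpha1 + CH - CL - We"),
            component = c("z", "y", "x")),
  E7 = list(exprs = c("Cp - P - Rp", "beta2 - beta1 + Cg - Fg - Rg - Ws",
                      "alpha1 - alpha2 - CH + CL + We + Ws"),
            component = c("z", "y", "x")),
  E8 = list(exprs = c("Cp - Rp", "beta2 - beta1 + Cg - Rg",
                      "alpha2 - alpha1 + CH - CL - We - Ws"),
            component = c("z", "y", "x"))
)

#' Symbolic eigenvalue expressions at a pure equilibrium
#'
#' Returns the closed-form eigenvalue expressions of the Jacobian at a
#' corner, as character strings over the parameter names, in the order the
#' classification table prints them, together with the state component each
#' expression differentiates along.  Evaluated at any valid parameter set
#' they equal the Jacobian diagonal at that corner.
#'
#' @param corner a corner label `"E1"`..`"E8"`.
#' @return A data frame with columns `expression` and `component`.
#' @export
corner_eigen_expressions <- function(corner) {
  if (!corner %in% names(CORNER_EIGEN)) {
    stop("unknown corner '", corner, "'; expected one of ",
         paste(names(CORNER_EIGEN), collapse = ", "), call. = FALSE)
  }
  entry <- CORNER_EIGEN[[corner]]
  data.frame(expression = entry$exprs, component = entry$component,
             row.names = NULL)
}

#' Evaluate the symbolic corner eigenvalues numerically
#'
#' @param params a [game_parameters()] object.
#' @param corner a corner label `"E1"`..`"E8"`.
#' @param order `"printed"` for the classification-table row order,
#'   `"component"` for `(x, y, z)` order.
#' @return A named numeric vector of three eigenvalues.
#' @export
corner_eigenvalues <- function(params, corner, order = c("component", "printed")) {
  order <- match.arg(order)
  params <- game_parameters_from(params)
  tab <- corner_eigen_expressions(corner)
  env <- as.list(setNames(as.numeric(params), names(params)))
  vals <- vapply(tab$expression,
                 function(e) eval(parse(text = e), envir = env),
                 numeric(1), USE.NAMES = FALSE)
  names(vals) <- tab$component
  if (order == "component") vals <- vals[c("x", "y", "z")]
  vals
}

#' Classify a pure equilibrium by its eigenvalue signs
#'
#' An equilibrium is an evolutionary stable strategy (ESS) when all three
#' Jacobian eigenvalues are negative; it is unstable when any eigenvalue is
#' positive.  Eigenvalues within `tol` of zero make the point
#' non-hyperbolic, where the linearisation is inconclusive along that
#' direction; a non-hyperbolic point that also has a positive eigenvalue is
#' still reported unstable.
#'
#' @param params a [game_parameters()] object.
#' @param corner a corner label `"E1"`..`"E8"`.
#' @param tol hyperbolicity tolerance for treating an eigenvalue as zero.
#' @return A list of class `equilibrium_report` with elements `corner`,
#'   `point`, `eigenvalues` (in `(x, y, z)` component order),
#'   `sign_pattern`, `non_hyperbolic` and `verdict`.
#' @examples
#' classify_equilibrium(baseline_parameters(), "E8")
#' @export
classify_equilibrium <- function(params, corner, tol = 1e-9) {
  stopifnot(tol > 0)
  params <- game_parameters_from(params)
  point <- pure_equilibria()[corner, ]
  eig <- corner_eigenvalues(params, corner, order = "component")
  signs <- ifelse(abs(eig) <= tol, "0", ifelse(eig > 0, "+", "-"))
  non_hyperbolic <- any(abs(eig) <= tol)
  verdict <- if (all(eig < -tol)) {
    "ESS"
  } else if (any(eig > tol)) {
    "unstable"
  } else {
    "non-hyperbolic"
  }
  structure(
    list(corner = corner, point = point, eigenvalues = eig,
         sign_pattern = signs, non_hyperbolic = non_hyperbolic,
         verdict = verdict),
    class = "equilibrium_report"
  )
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("%s (%s): eigenvalues (%s), signs (%s), verdict %s%s\n",
              x$corner, paste(x$point, collapse = ", "),
              paste(signif(x$eigenvalues, 6), collapse = ", "),
              paste(x$sign_pattern, collapse = ", "),
              x$verdict,
              if (x$non_hyperbolic) " [non-hyperbolic]" else ""))
  invisible(x)
}

#' Classify all eight pure equilibria
#'
#' @inheritParams classify_equilibrium
#' @return A data frame of class `stability_report` with one row per corner
#'   (columns `corner`, `x`, `y`, `z`, `eig_x`, `eig_y`, `eig_z`, `signs`,
#'   `non_hyperbolic`, `verdict`) and attribute `ess`, the character vector
#'   of ESS corners.
#' @examples
#' classify_all(baseline_parameters())
#' @export
classify_all <- function(params, tol = 1e-9) {
  corners <- rownames(pure_equilibria())
  reports <- lapply(corners, function(cn) classify_equilibrium(params, cn, tol))
  out <- data.frame(
    corner = corners,
    x = pure_equilibria()[, "x"],
    y = pure_equilibria()[, "y"],
    z = pure_equilibria()[, "z"],
    eig_x = vapply(reports, function(r) r$eigenvalues[["x"]], numeric(1)),
    eig_y = vapply(reports, function(r) r$eigenvalues[["y"]], numeric(1)),
    eig_z = vapply(reports, function(r) r$eigenvalues[["z"]], numeric(1)),
    signs = vapply(reports, function(r) paste(r$sign_pattern, collapse = ""),
                   character(1)),
    non_hyperbolic = vapply(reports, function(r) r$non_hyperbolic, logical(1)),
    verdict = vapply(reports, function(r) r$verdict, character(1)),
    row.names = NULL
  )
  attr(out, "ess") <- out$corner[out$verdict == "ESS"]
  class(out) <- c("stability_report", "data.frame")
  out
}
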