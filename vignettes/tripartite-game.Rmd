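---
title: "A tripartite evolutionary game for PPP regulation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A tripartite evolutionary game for PPP regulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pppgame)
```

## The game and its assumptions

Public-private partnership (PPP) projects that combine medical and
elderly-care services are run by a private operator, overseen by a
government agency, and consumed by a public that can complain about poor
service.  The package models the three groups as boundedly rational
populations: nobody computes an equilibrium in one shot; instead each
group gradually shifts toward whichever of its two strategies currently
pays better.  The state is the triple of strategy shares
$(x, y, z) \in [0,1]^3$ — high-quality provision, active regulation,
active monitoring.

The payoff model makes several stylised assumptions, which the package
implements literally:

* a regulating government always detects a default, and detects it
  before the public does;
* public complaints are always genuine and successful;
* currency-like payoffs (costs, subsidies, fines) and "reputation
  levels" are added on one common dimensionless utility scale;
* reputation terms ($\alpha_1 > \alpha_2$ for the operator,
  $\beta_1 > \beta_2$ for the government) accrue **only** when the
  public participates in monitoring — without an audience there is no
  reputation effect;
* the monitoring reward $R_p$ is paid to a participating public by the
  government regardless of whether that government is itself
  supervising, and a reported default under *no* supervision costs the
  operator nothing (only the exposure penalty $F_g$ hits the
  government);
* the reporting compensation $P$ is credited to the public without
  being debited from any other player.

The last three points are accounting conventions of the payoff table
rather than consequences of the others; alternative conventions (e.g.
fining a publicly reported operator) would change the switching
functions below and are deliberately not offered as options.

## From payoff table to replicator dynamics

`build_payoff_table()` enumerates the eight pure outcomes.  Writing
$Y_{11}$ for the expected payoff of a high-quality operator against the
mixed strategies $(y, z)$, $Y_{12}$ for a defaulting one, and
$\bar Y_1 = x Y_{11} + (1-x) Y_{12}$, the replicator equation is
$\dot x = x (Y_{11} - \bar Y_1)$, and similarly for $y$ and $z$.  The
payoff differences collapse to closed forms:

$$\dot x = x(x-1)\,G(y,z), \qquad
  G = C_H - C_L - W_e - z(\alpha_1-\alpha_2) - y W_s$$
$$\dot y = y(y-1)\,J(x,z), \qquad
  J = C_g - R_g - z(\beta_1-\beta_2) - (1-x) z F_g - (1-x) W_s$$
$$\dot z = z(z-1)\,D(x), \qquad\;\;
  D = C_p - R_p - P + P x$$

`replicator_rates()` implements the closed forms;
`replicator_rates_from_table()` recomputes the same rates by weighting
payoff-table cells with the opponents' mixtures.  The two routes are
algebraically identical, but the package treats that as a *testable*
claim, not an assumption: the test suite and the acceptance script
compare them on thousands of random parameter/state draws.

Three parameters — the fee floor $M_i$, the government's fixed income
$F_i$, and the public's damage $R_1$ — appear in payoff levels but
cancel from every within-group payoff difference, so they can never
affect the dynamics.  They are carried for payoff-table display only,
with arbitrary positive defaults (`Mi = 100`, `Fi = 100`, `R1 = 50`),
and the invariance is asserted bitwise in the tests.

Each switching function is affine in one opposing mixture, giving the
critical thresholds $y^*(z)$, $z^*(x)$ and $x^* = (P + R_p - C_p)/P$.
`critical_thresholds()` returns them **unclipped** with an `in_range`
flag: a threshold outside $[0,1]$ is informative (the drift direction is
fixed over the whole feasible range — at baseline $x^* = 305/300 > 1$,
so monitoring is favoured for every feasible $x$), and clipping would
destroy that information.

## Stability of the pure equilibria

The eight cube corners are fixed points for every parameter set.  The
Jacobian's off-diagonal entries all carry prefactors $x(x-1)$, $y(y-1)$
or $z(z-1)$ that vanish at corners, so each corner Jacobian is diagonal
and its eigenvalues are the three diagonal closed forms.
`corner_eigen_expressions()` stores these per corner, in the order the
classification is conventionally tabulated (which differs row by row;
each expression is tagged with the state component it differentiates
along), and `classify_equilibrium()` evaluates them numerically.

A corner is an **ESS** when all three eigenvalues are below
$-\mathrm{tol}$, **unstable** when any exceeds $+\mathrm{tol}$, and
**non-hyperbolic** when an eigenvalue lies within $\mathrm{tol}$ of
zero, where linearisation is inconclusive along that direction.  The
verdicts interact: a corner with a zero *and* a positive eigenvalue is
reported unstable with the `non_hyperbolic` flag set, which is exactly
the situation of corners E4 and E6 under the baseline assignment
($\alpha_1 - \alpha_2 - C_H + C_L + W_e = 0$ there).  The default
`tol = 1e-9` is far below every structural eigenvalue scale in the
baseline's magnitude regime (units to hundreds) while comfortably above
floating-point noise in the evaluated expressions.

Interior (mixed) equilibria are not enumerated: the analysis concerns
the pure corners, and in replicator systems the interior roots of
$G = J = D = 0$ are non-attracting knife edges here.

## Numerical integration

`simulate_game()` integrates the system with `deSolve`'s `lsoda`
(adaptive stiff/non-stiff switching) at `rtol = 1e-8`,
`atol = 1e-10`.  The vector field is polynomial and tangent to the unit
cube, so trajectories cannot analytically escape; post-hoc clamping to
$[0,1]$ corrects solver round-off only, and the simulator warns if the
pre-clamp overshoot ever exceeds $10^{-6}$.

Defaults: horizon 50 time units, output grid spacing `dt = 0.01`, and
initial state $(0.2, 0.2, 0.2)$.  The horizon and the 50-run ensemble
default both come from reading "evolving 50 times" as *either* a time
horizon *or* a replicate count; the package adopts both readings as
defaults and leaves each configurable.  No initial conditions are
prescribed by the source analysis, so the 20%-cooperative start is a
package convention: pessimistic enough that every share has real ground
to cover, interior enough to avoid the absorbing faces.  Time units are
abstract — nothing calibrates them to months or years — so all timing
comparisons in the package are **ordinal** (which sweep value converges
first), never quantitative durations.

Two timing notions coexist deliberately:

* `convergence_time()` — earliest time from which the max-norm distance
  to a target stays within `eps`: the right notion for "has the system
  settled".
* `crossing_time()` — first passage of a single share across a level,
  linearly interpolated between output points: the right notion for
  "how fast does this group move", and the one the sensitivity sweeps
  use (level $1 - \mathrm{eps}$, default `eps = 0.01`).

They can disagree in instructive ways.  Raising the subsidy $W_e$
speeds the private share toward 1, but thereby shrinks the fine revenue
$(1-x) W_s$ that motivates the government, so the *whole-state*
settling time can lengthen even as the $x$-crossing time shortens.  The
interpolation matters because convergence under the baseline magnitudes
is fast (crossing times of order 0.03–0.2 time units): on a 0.01 grid,
raw grid indices would tie where the underlying times differ.

## Sensitivity experiments

`figure_scenarios()` bundles the six one-parameter experiments: subsidy
$W_e \in \{30, 50, 70\}$ and fine $W_s \in \{40, 80, 120\}$ tracking
$x$; regulation cost $C_g \in \{30, 45, 60\}$ and benefit
$R_g \in \{20, 40, 60\}$ tracking $y$; monitoring cost
$C_p \in \{6, 10, 14\}$ and reward $R_p \in \{11, 15, 19\}$ tracking
$z$.  `sweep_parameter()` guarantees sweep purity — runs differ in the
named parameter only — and records invariant-breaking values as
per-value errors instead of aborting.

The $C_p$/$R_p$ grids are a package choice (no grids are prescribed for
these two experiments): symmetric integer grids around the baseline
values with the largest spacing that keeps the reward strictly above
the cost.  The constraint is structural, not cosmetic: at
$C_p = R_p$ the $z$-eigenvalue of the all-cooperate corner is exactly
zero, the public's drive decays with $(1-x)$, and the monitoring share
converges to a limit strictly below 1 — the qualitative regime changes.
Inside the $C_p < R_p$ region the final state is identical across the
grid and the crossing-time spread is a few percent of the baseline
time; `monotonicity_report()` declares a sweep **indistinguishable**
when that spread is below 5% of the base-parameter time, the package's
operationalisation of "the differences are too subtle to see".

The $C_g$ grid illustrates the opposite situation, and users should be
aware of it: the grid *crosses* the stability boundary of the
all-cooperate corner.  Its government eigenvalue
$\beta_2 - \beta_1 + C_g - R_g$ reaches zero at $C_g = 45$ and is
positive at $C_g = 60$.  Consequently $y$ plateaus below 0.99 at
$C_g = 45$ (finite integrated drive) and rises only transiently before
collapsing toward 0 at $C_g = 60$.  The intuitive claim "cheaper
regulation converges faster" therefore holds in full only strictly
below the boundary; above it the crossing time is reported as `NA` and
the ordering verdict as non-monotone.  The package reports what the
model does rather than forcing the expected ordering.

## Synthetic parameter regimes

`sample_parameters()` draws each parameter uniformly from
$[0.5, 2] \times$ its baseline value — keeping draws in the baseline's
magnitude regime — and rejection-samples (budget 10,000) until the
requested regime holds: `unconstrained` (structural inequalities
$C_H > C_L$, $\alpha_1 > \alpha_2$, $\beta_1 > \beta_2$ only),
`ess_stable` (all three all-cooperate stability margins negative), or
`ess_violated` (exactly one named margin positive).  All sampling is a
pure function of the seed, and the caller's RNG stream is restored.

The generator emulates the *structure* of the study conditions —
parameter magnitudes, the stability regimes, interior starting points —
not real PPP project data: no empirical calibration exists for these
utility-scale payoffs.  Passing tests therefore demonstrate internal
consistency of the model and its implementation, monotone incentive
effects, and basin-of-attraction behaviour under the stated conditions;
they say nothing about how actual stakeholders weight reputation
against cash.

## Known limitations

* Deterministic, infinite-population replicator dynamics only — no
  finite-population (Moran) noise, no asymmetric information, no more
  than two strategies per player.
* Corner analysis only; interior equilibria are not characterised.
* Timing is ordinal; the model has no empirical time scale.
* The payoff-table conventions noted above (unfunded compensation $P$,
  reward without supervision, unpunished reported-only defaults) are
  fixed; sensitivity to those conventions is out of scope.
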