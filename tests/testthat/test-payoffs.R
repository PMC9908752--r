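cell <- function(tab, nv, sup, part) {
  row <- tab[tab$no_violation == nv & tab$supervises == sup &
               tab$participates == part, ]
  c(row$private, row$government, row$public)
}

test_that("payoff table matches the 2x2x2 outcome matrix", {
  p <- as.list(setNames(as.numeric(baseline), names(baseline)))
  tab <- build_payoff_table(baseline)
  expect_equal(nrow(tab), 8)
  expect_equal(anyDuplicated(tab[1:3]), 0)

  # quiet operator, unsupervised, unmonitored: bare user-fee margin
  expect_equal(cell(tab, FALSE, FALSE, FALSE),
               c(p$Mi - p$CL, p$Fi, -p$R1))
  # full cooperation cell carries subsidy, reputations and reward flows
  expect_equal(cell(tab, TRUE, TRUE, TRUE),
               c(p$Mi + p$We + p$alpha1 - p$CH,
                 p$Fi + p$Rg + p$beta1 - p$Cg - p$Rp,
                 p$Rp - p$Cp))
  # high quality under supervision alone, with the baseline assignment
  expect_equal(cell(tab, TRUE, TRUE, FALSE),
               c(p$Mi - 40, p$Fi - 10, 0))
  # exposed default: fine moves from operator to government
  expect_equal(cell(tab, FALSE, TRUE, FALSE),
               c(p$Mi - p$CL - p$Ws, p$Fi + p$Rg + p$Ws - p$Cg, -p$R1))
  # unsupervised default reported by the public: Fg hits the government
  expect_equal(cell(tab, FALSE, FALSE, TRUE),
               c(p$Mi + p$alpha2 - p$CL,
                 p$Fi + p$beta2 - p$Rp - p$Fg,
                 p$Rp - p$Cp - p$R1 + p$P))
})

test_that("reputation, fine and exposure terms appear only where they belong", {
  tweaked <- baseline
  tweaked[c("alpha1", "alpha2", "beta1", "beta2")] <-
    baseline[c("alpha1", "alpha2", "beta1", "beta2")] + c(7, 3, 7, 3)
  t0 <- build_payoff_table(baseline)
  t1 <- build_payoff_table(tweaked)
  idle <- !t0$participates
  expect_equal(t1[idle, c("private", "government", "public")],
               t0[idle, c("private", "government", "public")])

  tweaked <- baseline
  tweaked["Ws"] <- baseline["Ws"] + 11
  t1 <- build_payoff_table(tweaked)
  unaffected <- t0$no_violation | !t0$supervises
  expect_equal(t1[unaffected, c("private", "government", "public")],
               t0[unaffected, c("private", "government", "public")])

  tweaked <- baseline
  tweaked["Fg"] <- baseline["Fg"] + 13
  t1 <- build_payoff_table(tweaked)
  hit <- t1$government != t0$government
  expect_equal(which(hit),
               which(!t0$no_violation & !t0$supervises & t0$participates))
})

test_that("expected payoffs reduce correctly at degenerate mixtures", {
  p <- as.list(setNames(as.numeric(baseline), names(baseline)))

  # full monitoring collapses the private high-quality payoff
  pr <- expected_private_payoffs(baseline, c(0.3, 0.7, 1))
  expect_equal(pr$Y11, p$Mi + p$We + p$alpha1 - p$CH)
  # no supervision, no monitoring: defaulting is unpunished
  pr <- expected_private_payoffs(baseline, c(0.3, 0, 0))
  expect_equal(pr$Y12, p$Mi - p$CL)

  gov <- expected_government_payoffs(baseline, c(1, 0.4, 0))
  expect_equal(gov$Y21, p$Fi + p$Rg - p$Cg)
  gov <- expected_government_payoffs(baseline, c(1, 0.4, 1))
  expect_equal(gov$Y22, p$Fi + p$beta2 - p$Rp)

  pub <- expected_public_payoffs(baseline, c(1, 0.4, 0.6))
  expect_equal(pub$Y31, p$Rp - p$Cp)
  pub <- expected_public_payoffs(baseline, c(0, 0.4, 0.6))
  expect_equal(pub$Y32, -p$R1)
})

test_that("payoff advantages at the centre state take the derived values", {
  s <- c(0.5, 0.5, 0.5)
  pr <- expected_private_payoffs(baseline, s)
  expect_equal(pr$Y11 - pr$Y12, 35)
  expect_equal(pr$Y1_mean, 0.5 * pr$Y11 + 0.5 * pr$Y12)

  gov <- expected_government_payoffs(baseline, s)
  expect_equal(gov$Y21 - gov$Y22, 67.5)

  pub <- expected_public_payoffs(baseline, c(0.5, 0.3, 0.9))
  expect_equal(pub$Y31 - pub$Y32, 155) # independent of y and z
})

test_that("switching functions take their derived baseline values", {
  g <- switching_functions(baseline, c(0.5, 0.5, 0.5))
  expect_equal(g[["G"]], -35)
  g <- switching_functions(baseline, c(1, 0.2, 0.9))
  expect_equal(g[["D"]], -5) # D depends on x only
  g <- switching_functions(baseline, c(0, 0.5, 0))
  expect_equal(g[["J"]], -70)
})

test_that("replicator rates vanish at corners and match hand substitution", {
  corners <- pure_equilibria()
  for (i in seq_len(nrow(corners))) {
    expect_equal(unname(replicator_rates(baseline, corners[i, ])), c(0, 0, 0))
  }
  expect_equal(unname(replicator_rates(baseline, c(0.5, 0.5, 0.5))),
               c(8.75, 16.875, 38.75))
  expect_equal(unname(replicator_rates_from_table(baseline, c(0.5, 0.5, 0.5))),
               c(8.75, 16.875, 38.75))
})

test_that("critical thresholds solve the switching equations", {
  th <- critical_thresholds(baseline, c(1, 0, 0))
  row <- function(nm) th[th$threshold == nm, ]
  expect_equal(row("y_star")$value, 0.125) # at z = 0
  expect_equal(row("z_star")$value, 0.4)   # at x = 1
  expect_equal(row("x_star")$value, 305 / 300)
  expect_true(row("y_star")$in_range)
  expect_false(row("x_star")$in_range) # monitoring favoured for all x

  # Ws = 0 leaves the private sector without a finite indifference point
  p <- baseline
  p["Ws"] <- 0
  th <- critical_thresholds(p, c(0.5, 0.5, 0.5))
  expect_false(th[th$threshold == "y_star", "finite"])
})
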