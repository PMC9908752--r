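short <- solver_settings(horizon = 5, dt = 0.01)

test_that("corner initial states are exact fixed points", {
  for (corner in c("E1", "E8", "E5")) {
    traj <- simulate_game(baseline, pure_equilibria()[corner, ], short)
    expect_equal(unique(traj$x), pure_equilibria()[corner, "x"])
    expect_equal(unique(traj$y), pure_equilibria()[corner, "y"])
    expect_equal(unique(traj$z), pure_equilibria()[corner, "z"])
  }
})

test_that("baseline interior trajectories converge to all-cooperate", {
  traj <- simulate_game(baseline, c(0.2, 0.2, 0.2))
  fin <- traj[nrow(traj), ]
  expect_lt(max(abs(c(fin$x, fin$y, fin$z) - 1)), 1e-3)
  expect_equal(traj$time[1], 0)
  expect_true(all(diff(traj$time) > 0))

  # a coarse interior grid all lands on the same corner
  grid <- as.matrix(expand.grid(x = c(0.1, 0.5, 0.9),
                                y = c(0.1, 0.5, 0.9),
                                z = c(0.1, 0.5, 0.9)))
  fins <- final_states(simulate_ensemble(baseline, grid,
                                         solver_settings(horizon = 50)))
  expect_true(all(abs(as.matrix(fins) - 1) < 1e-3))
})

test_that("trajectories stay inside the unit cube", {
  for (draw in random_draws(5, seed = 110)) {
    traj <- simulate_game(draw$params, 0.1 + 0.8 * draw$state, short)
    expect_true(all(traj$x >= 0 & traj$x <= 1))
    expect_true(all(traj$y >= 0 & traj$y <= 1))
    expect_true(all(traj$z >= 0 & traj$z <= 1))
  }
})

test_that("each share is monotone while its switching function keeps sign", {
  traj <- simulate_game(baseline, c(0.2, 0.2, 0.2), short)
  sw <- t(apply(traj[c("x", "y", "z")], 1, function(s)
    switching_functions(baseline, s)))
  # slack well above solver round-off at the absorbing face
  inc_x <- diff(traj$x) >= -1e-8
  inc_y <- diff(traj$y) >= -1e-8
  inc_z <- diff(traj$z) >= -1e-8
  neg <- function(col) col[-length(col)] < 0 & col[-1] < 0
  expect_true(all(inc_x[neg(sw[, "G"])]))
  expect_true(all(inc_y[neg(sw[, "J"])]))
  expect_true(all(inc_z[neg(sw[, "D"])]))
})

test_that("trajectories ignore the nuisance parameters Mi, Fi, R1", {
  p2 <- baseline
  p2[c("Mi", "Fi", "R1")] <- c(1, 500, 0)
  t1 <- simulate_game(baseline, c(0.3, 0.4, 0.5), short)
  t2 <- simulate_game(p2, c(0.3, 0.4, 0.5), short)
  expect_identical(t1[c("time", "x", "y", "z")], t2[c("time", "x", "y", "z")])
})

test_that("convergence time is the earliest durable entry into the ball", {
  traj <- simulate_game(baseline, c(1, 1, 1), short)
  expect_equal(convergence_time(traj, c(1, 1, 1)), 0)

  traj <- simulate_game(baseline, c(0.2, 0.2, 0.2))
  tc <- convergence_time(traj, c(1, 1, 1), eps = 0.01)
  expect_true(is.finite(tc))
  i <- which(traj$time >= tc)
  expect_true(all(pmax(abs(traj$x - 1), abs(traj$y - 1),
                       abs(traj$z - 1))[i] <= 0.01))

  # never-converging case: a corner far from the target
  stuck <- simulate_game(baseline, c(0, 0, 0), short)
  expect_true(is.na(convergence_time(stuck, c(1, 1, 1))))

  # raising the subsidy speeds the private share toward 1 (the whole-state
  # time is governed by the slowest component, not by x)
  p <- baseline; p["We"] <- 70
  t_hi <- crossing_time(simulate_game(p, c(0.2, 0.2, 0.2)), "x", 0.99)
  expect_lt(t_hi, crossing_time(traj, "x", 0.99))
})

test_that("crossing times interpolate between output points", {
  traj <- simulate_game(baseline, c(0.2, 0.2, 0.2))
  t99 <- crossing_time(traj, "x", 0.99)
  below <- max(traj$time[traj$x < 0.99])
  above <- min(traj$time[traj$x >= 0.99])
  expect_gte(t99, below)
  expect_lte(t99, above)
  expect_true(is.na(crossing_time(simulate_game(baseline, c(0, 0, 0), short),
                                  "x", 0.99)))
  expect_equal(crossing_time(simulate_game(baseline, c(1, 1, 1), short), "x"),
               0)
})

test_that("ensembles preserve order, handle empty input and reproduce", {
  expect_length(simulate_ensemble(baseline, list(), short), 0)

  inits <- sample_initial_states(4, seed = 7)
  ens <- simulate_ensemble(baseline, inits, short)
  expect_length(ens, 4)
  for (i in 1:4) {
    expect_equal(unname(attr(ens[[i]], "init")), unname(inits[i, ]))
  }
  ens2 <- simulate_ensemble(baseline, sample_initial_states(4, seed = 7),
                            short)
  expect_identical(lapply(ens, as.data.frame), lapply(ens2, as.data.frame))
})

test_that("trajectory CSV export is tidy", {
  traj <- simulate_game(baseline, c(0.2, 0.2, 0.2), short)
  path <- tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read.csv(path)
  expect_equal(names(back), c("time", "x", "y", "z"))
  expect_equal(nrow(back), nrow(traj))
})
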