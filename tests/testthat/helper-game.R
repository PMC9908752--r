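# Shared fixtures: random draws stay reproducible through explicit seeds.

baseline <- baseline_parameters()

# n random (parameters, state) pairs from the unconstrained regime
random_draws <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(
      params = sample_parameters("unconstrained"),
      state = runif(3)
    )
  })
}

expect_rates_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
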