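# Shared fixtures. The OSSE experiment runs are expensive, so they are
# computed once per test session and memoised here; several test files
# reuse them.

.fixtures <- new.env(parent = emptyenv())

# Synthetic truth pair mirroring the experiment workflow: spin-up, one
# plain model year (first map at end of year 1), then k disturbed years.
make_truth_pair <- function(regime, n = 1600, k = 4, seed = 1,
                            noise = noise_model(), bias_on = "t1") {
  set.seed(seed)
  base <- spin_up(n, growth_model(), spin_up_config())
  model <- attr(base, "model")
  yr1 <- step_state(base$values, model, disturbance_regime(0, 0), 1)
  t1 <- biomass_ensemble(yr1$biomass, base$pixel_edge, base$time_index + 1)
  attr(t1, "model") <- model
  simulate_pair(t1, model, regime, noise, separation_years = k,
                bias_on = bias_on)
}

fixture_test1 <- function() {
  if (is.null(.fixtures$test1))
    .fixtures$test1 <- run_test1(test1_spec(seed = 1))
  .fixtures$test1
}

fixture_test2 <- function() {
  if (is.null(.fixtures$test2))
    .fixtures$test2 <- run_test2(test2_spec(seed = 1))
  .fixtures$test2
}

fixture_test3 <- function() {
  if (is.null(.fixtures$test3))
    .fixtures$test3 <- run_test3(test3_spec(seed = 1,
                                            replicates_per_case = 3))
  .fixtures$test3
}

# Twenty repeated OSSE runs of the high-intensity E_M = 0.045 case, used
# for region-coverage checks.
fixture_coverage_runs <- function() {
  if (is.null(.fixtures$coverage)) {
    truth <- disturbance_regime(0.05, 0.9)
    fits <- vector("list", 20)
    for (i in 1:20) {
      pair <- make_truth_pair(truth, seed = 100 + i)
      fits[[i]] <- estimate_regime(pair, estimator_config(seed = 500 + i))
    }
    .fixtures$coverage <- fits
  }
  .fixtures$coverage
}

# One full-size fit reused by estimator unit tests.
fixture_fit_high <- function() {
  if (is.null(.fixtures$fit_high))
    .fixtures$fit_high <- fixture_coverage_runs()[[1]]
  .fixtures$fit_high
}

# Build a likelihood_surface object directly from a matrix of positive
# weights (for credible-region unit tests).
surface_from_matrix <- function(w, e_p_axis = NULL, e_i_axis = NULL) {
  if (is.null(e_p_axis)) e_p_axis <- seq(0, 1, length.out = nrow(w))
  if (is.null(e_i_axis)) e_i_axis <- seq(0, 1, length.out = ncol(w))
  structure(list(e_p_axis = e_p_axis, e_i_axis = e_i_axis,
                 log_lik = log(w), lik_norm = w / sum(w)),
            class = "likelihood_surface")
}

expect_within <- function(object, target, tol) {
  expect_true(abs(object - target) <= tol,
              label = sprintf("%g within %g of %g", object, tol, target))
}
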