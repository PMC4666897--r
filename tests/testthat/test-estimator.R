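test_that("the change distribution is the order-preserving difference", {
  a <- biomass_ensemble(c(10, 20, 30))
  b <- biomass_ensemble(c(5, 25, 30))
  pair <- observation_pair(a, b, 1)
  expect_identical(delta_distribution(pair), c(-5, 5, 0))
  same <- observation_pair(a, a, 1)
  expect_identical(delta_distribution(same), c(0, 0, 0))
  down <- observation_pair(a, biomass_ensemble(a$values - 7), 1)
  expect_identical(delta_distribution(down), rep(-7, 3))
})

test_that("simulated pairs recover the truth-side mean change within noise", {
  set.seed(21)
  pair <- make_truth_pair(disturbance_regime(0.1, 0.5), n = 5000, k = 4)
  d <- delta_distribution(pair)
  true_change <- mean(pair$truth$state_t2 - pair$truth$state_t1)
  se <- sqrt(2) * 800 / sqrt(5000)
  expect_within(mean(d), true_change, 4 * se)
})

test_that("smoothing keeps the log-likelihood finite for unseen observations", {
  cfg <- estimator_config(replicates = 2, seed = 3)
  # observations far outside anything the simulator can produce
  delta <- c(rep(0, 50), 1e6, -1e6)
  ll <- log_likelihood(delta, disturbance_regime(0.1, 0.5), cfg,
                       separation_years = 1)
  expect_true(is.finite(ll))
})

test_that("a degenerate all-equal change sample falls back to a single bin", {
  delta <- rep(5, 100)
  cfg <- estimator_config(replicates = 2, seed = 3)
  ll <- log_likelihood(delta, disturbance_regime(0.2, 0.2), cfg)
  expect_true(is.finite(ll))
  expect_identical(forestdist:::.delta_breaks(delta, "auto"), c(-Inf, Inf))
})

test_that("the generating regime beats a distant rival in likelihood", {
  truth <- disturbance_regime(0.05, 0.9)
  rival <- disturbance_regime(0.9, 0.05)
  cfg <- estimator_config(replicates = 5)
  wins <- 0L
  for (i in 1:20) {
    pair <- make_truth_pair(truth, n = 400, k = 4, seed = 2000 + i)
    d <- delta_distribution(pair)
    cfg$seed <- 3000 + i
    ll_truth <- log_likelihood(d, truth, cfg, 4, obs_t1 = pair$obs_t1$values)
    cfg$seed <- 3000 + i
    ll_rival <- log_likelihood(d, rival, cfg, 4, obs_t1 = pair$obs_t1$values)
    if (ll_truth > ll_rival) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("likelihood surfaces are normalised and reproducible", {
  set.seed(41)
  pair <- make_truth_pair(disturbance_regime(0.1, 0.5), n = 200, k = 2,
                          seed = 41)
  cfg <- estimator_config(grid_step = 0.25, replicates = 3, seed = 11)
  d <- delta_distribution(pair)
  s1 <- likelihood_surface(d, cfg, 2)
  s2 <- likelihood_surface(d, cfg, 2)
  expect_identical(s1$log_lik, s2$log_lik)
  expect_lt(abs(sum(s1$lik_norm) - 1), 1e-9)
  expect_true(all(s1$lik_norm >= 0))
  expect_identical(dim(s1$log_lik),
                   c(length(s1$e_p_axis), length(s1$e_i_axis)))
  expect_identical(s1$e_p_axis, seq(0, 1, by = 0.25))
})

test_that("the surface argmax lands near the generating regime", {
  fit <- fixture_fit_high()   # truth E_P = 0.05, E_I = 0.9
  expect_lte(abs(fit$argmax$e_p - 0.05), 0.1)
  expect_lte(abs(fit$argmax$e_i - 0.9), 0.15)
})

test_that("a point-mass surface yields a single-cell region with zero ranges", {
  w <- matrix(1e-12, 5, 5)
  w[2, 3] <- 1
  reg <- credible_region(surface_from_matrix(w))
  expect_identical(nrow(reg$cells), 1L)
  expect_true(all(reg$summaries[, "range"] == 0))
})

test_that("a uniform surface is kept whole by the tie rule", {
  w <- matrix(1, 4, 4)
  reg <- credible_region(surface_from_matrix(w), level = 0.95)
  # ceiling(0.95 * 16) = 16 via ties: every cell is tied with the last
  expect_identical(nrow(reg$cells), 16L)
  expect_equal(reg$coverage, 1)
})

test_that("region construction matches brute-force subset enumeration on 3x3", {
  set.seed(77)
  for (trial in 1:20) {
    w <- matrix(rexp(9), 3, 3)
    s <- surface_from_matrix(w)
    reg <- credible_region(s, level = 0.95)
    # oracle: among all subsets reaching the level, take minimal size,
    # then maximal mass; compare cell sets
    lik <- as.vector(s$lik_norm)
    best_size <- Inf
    best_mass <- -Inf
    best_set <- NULL
    for (mask in 1:(2^9 - 1)) {
      idx <- which(bitwAnd(mask, 2^(0:8)) > 0)
      mass <- sum(lik[idx])
      if (mass >= 0.95 - 1e-12) {
        if (length(idx) < best_size ||
            (length(idx) == best_size && mass > best_mass + 1e-12)) {
          best_size <- length(idx)
          best_mass <- mass
          best_set <- idx
        }
      }
    }
    got <- sort((match(reg$cells$e_p, s$e_p_axis)) +
                (match(reg$cells$e_i, s$e_i_axis) - 1L) * 3L)
    expect_identical(length(got), length(best_set))
    expect_equal(sum(lik[got]), best_mass, tolerance = 1e-12)
  }
})

test_that("regions are minimal: dropping their weakest cell breaks coverage", {
  set.seed(78)
  w <- matrix(rexp(25), 5, 5)
  reg <- credible_region(surface_from_matrix(w), level = 0.9)
  expect_gte(reg$coverage, 0.9)
  expect_lt(reg$coverage - min(reg$cells$lik), 0.9)
})

test_that("fit objects expose coherent coefficients, intervals and summaries", {
  fit <- fixture_fit_high()
  expect_s3_class(fit, "regime_fit")
  co <- coef(fit)
  expect_named(co, c("E_P", "E_I", "E_M"))
  expect_identical(unname(co["E_M"]), unname(co["E_P"] * co["E_I"]))
  s <- fit$summaries
  expect_equal(unname(s[, "range"]), unname(s[, "max"] - s[, "min"]))
  ci <- confint(fit)
  expect_identical(unname(ci[, 1]), unname(s[, "min"]))
  expect_identical(unname(ci[, 2]), unname(s[, "max"]))
  expect_output(print(fit), "Most likely regime")
  expect_output(print(summary(fit)), "cumulative-likelihood region")
})

test_that("fitted surfaces render without error", {
  fit <- fixture_fit_high()
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("region membership testing respects the grid geometry", {
  w <- matrix(1e-9, 3, 3)
  w[2, 2] <- 1
  s <- surface_from_matrix(w, e_p_axis = c(0, 0.5, 1),
                           e_i_axis = c(0, 0.5, 1))
  reg <- credible_region(s)
  expect_true(region_contains(reg, disturbance_regime(0.5, 0.5),
                              grid_step = 0.5))
  expect_true(region_contains(reg, disturbance_regime(0.3, 0.6),
                              grid_step = 0.5))
  expect_false(region_contains(reg, disturbance_regime(0, 0),
                               grid_step = 0.5))
})

test_that("estimated intervals tighten as the truth signal strengthens", {
  r1 <- fixture_test1()
  hi <- r1[r1$actual_e_i == 0.9, ]
  lo <- r1[r1$actual_e_p == 0.9 & r1$actual_e_m > 0, ]
  # intensity and probability are better resolved at stronger mean loss
  expect_lte(hi$est_ei_range[which.min(abs(hi$actual_e_m - 0.180))],
             hi$est_ei_range[which.min(abs(hi$actual_e_m - 0.018))])
  expect_lte(lo$est_ep_range[which.min(abs(lo$actual_e_m - 0.180))],
             lo$est_ep_range[which.min(abs(lo$actual_e_m - 0.018))])
})
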