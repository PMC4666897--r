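test_that("baseline generator hits its mean and stays non-negative", {
  n <- 1e5
  for (shape in c("gamma", "lognormal", "truncated_normal")) {
    set.seed(5)
    ens <- generate_baseline(n, mean = 2500, cv = 0.5, shape = shape)
    expect_true(all(ens$values >= 0))
    # CLT oracle: sample mean within 3 standard errors
    expect_within(mean(ens$values), 2500,
                  3 * sd(ens$values) / sqrt(n))
  }
  expect_error(generate_baseline(10, shape = "uniform"), "shape")
})

test_that("baseline generator degenerates to the mean as cv goes to zero", {
  set.seed(1)
  ens <- generate_baseline(1000, mean = 2500, cv = 1e-5)
  expect_within(max(abs(ens$values - 2500)), 0, 1)
})

test_that("baseline generation is reproducible under a seed", {
  set.seed(123)
  a <- generate_baseline(1000)
  set.seed(123)
  b <- generate_baseline(1000)
  expect_identical(a$values, b$values)
})

test_that("disturbance operator obeys its limiting cases", {
  b <- c(100, 2500, 0, 900)
  set.seed(2)
  none <- apply_disturbance(b, disturbance_regime(0, 0.9))
  expect_identical(none$biomass, b)
  expect_false(any(none$mask))
  all_clear <- apply_disturbance(b, disturbance_regime(1, 1))
  expect_identical(all_clear$biomass, rep(0, 4))
  expect_true(all(all_clear$mask))
})

test_that("disturbed fraction and ensemble loss match the binomial oracle", {
  n <- 1e5
  regime <- disturbance_regime(0.9, 0.05)
  set.seed(8)
  b <- rgamma(n, 4, scale = 625)
  out <- apply_disturbance(b, regime)
  frac <- mean(out$mask)
  expect_within(frac, 0.9, 4 * sqrt(0.9 * 0.1 / n))
  loss <- 1 - sum(out$biomass) / sum(b)
  per_pix <- 1 - out$biomass / b
  expect_within(loss, expected_mean_loss(regime),
                4 * sd(per_pix) / sqrt(n))
})

test_that("noise-free observation is the identity and bias shifts exactly", {
  b <- c(0, 500, 2500)
  expect_identical(observe(b, noise_model(sd = 0, bias = 0)), b)
  shifted <- observe(b, noise_model(sd = 0, bias = 160), apply_bias = TRUE)
  expect_identical(shifted, b + 160)
  # bias ignored unless the date is flagged
  expect_identical(observe(b, noise_model(sd = 0, bias = 160)), b)
})

test_that("linear-domain noise has the configured spread and is not clipped", {
  n <- 1e5
  b <- rep(2000, n)
  set.seed(3)
  o <- observe(b, noise_model(sd = 800))
  # chi-squared oracle: SE of a Gaussian sample sd is sd/sqrt(2n)
  expect_within(sd(o - b), 800, 4 * 800 / sqrt(2 * n))
  expect_gt(sum(o < 0), 0)   # negative observations retained
})

test_that("dB-domain noise is Gaussian on the log scale and needs a floor at zero", {
  n <- 5e4
  b <- rep(2000, n)
  noise <- noise_model(sd = 0.5, domain = "dB")
  set.seed(4)
  o <- observe(b, noise)
  db_err <- 10 * log10(o / b)
  expect_within(sd(db_err), 0.5, 4 * 0.5 / sqrt(2 * n))
  expect_within(mean(db_err), 0, 4 * 0.5 / sqrt(n))
  expect_error(observe(c(0, 100), noise), "floor")
  expect_silent(observe(c(0, 100), noise_model(sd = 0.5, domain = "dB",
                                               floor = 1)))
})

test_that("a quiet noiseless pair has an identically zero change distribution", {
  base <- generate_baseline(100)
  zero <- growth_model(r = 0, b_max = 2500, g0 = 0)
  set.seed(6)
  pair <- simulate_pair(base, zero, disturbance_regime(0, 0),
                        noise_model(sd = 0), separation_years = 3)
  expect_identical(delta_distribution(pair), rep(0, 100))
})

test_that("simulated pairs compound losses like the binomial oracle", {
  n <- 1e5
  set.seed(7)
  base <- generate_baseline(n)
  zero <- growth_model(r = 0, b_max = 2500, g0 = 0)
  regime <- disturbance_regime(0.05, 0.9)
  pair <- simulate_pair(base, zero, regime, noise_model(sd = 0),
                        separation_years = 4)
  d <- delta_distribution(pair)
  rel <- mean(d) / mean(pair$obs_t1$values)
  expected <- (1 - expected_mean_loss(regime))^4 - 1
  per_pix <- d / base$values
  expect_within(rel, expected, 4 * sd(per_pix) / sqrt(n))
  # truth retained for OSSE scoring
  expect_identical(pair$truth$regime, regime)
  expect_identical(dim(pair$truth$masks), c(100000L, 4L))
})

test_that("undisturbed change distributions are symmetric about the growth signal", {
  n <- 2e4
  set.seed(9)
  base <- spin_up(n, growth_model(), spin_up_config())
  pair <- simulate_pair(base, growth_model(), disturbance_regime(0, 0),
                        noise_model(sd = 800), separation_years = 4)
  d <- delta_distribution(pair)
  skew <- mean((d - mean(d))^3) / sd(d)^3
  expect_within(skew, 0, 4 * sqrt(6 / n))
})

test_that("identical seeds give bit-identical observation pairs", {
  run <- function() {
    set.seed(11)
    base <- generate_baseline(500)
    simulate_pair(base, growth_model(), disturbance_regime(0.1, 0.5),
                  noise_model(), separation_years = 4)
  }
  a <- run()
  b <- run()
  expect_identical(a$obs_t1$values, b$obs_t1$values)
  expect_identical(a$obs_t2$values, b$obs_t2$values)
  expect_identical(a$truth, b$truth)
})

test_that("true-state trajectories stay non-negative under heavy disturbance", {
  set.seed(13)
  base <- generate_baseline(1000)
  pair <- simulate_pair(base, growth_model(), disturbance_regime(0.9, 0.99),
                        noise_model(), separation_years = 6)
  expect_true(all(pair$truth$state_t2 >= 0))
})

test_that("pairs demand equal pixel counts and whole-year separations", {
  a <- biomass_ensemble(1:10)
  b <- biomass_ensemble(1:9)
  expect_error(observation_pair(a, b, 1), "same pixels")
  expect_error(observation_pair(a, a, 0), "separation_years")
})

test_that("ensemble areas follow the square-root pixel geometry", {
  expect_equal(ensemble_side_m(1600, 25), 1000)
  expect_equal(ensemble_side_m(6400, 25), 2000)
  expect_equal(ensemble_side_m(400, 25), 500)
  expect_equal(ensemble_side_m(100, 25), 250)
})
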