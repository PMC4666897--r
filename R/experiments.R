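#' Specify an OSSE validation experiment
#'
#' An experiment is a list of cases, each pairing a true disturbance
#' regime with an ensemble size, an observation bias and a map separation.
#' For every case a synthetic truth is spun up, the regime is applied for
#' one year (the first map is taken at the end of year 1), noisy maps are
#' generated `k` years apart, and the estimator is scored against the
#' known truth.
#'
#' Per-case seeds are derived deterministically from the spec seed and the
#' case content (regime, n, bias, k, replicate), so identical cases give
#' identical rows across experiments run with the same seed.
#'
#' @param test_id Identifier: `"test1_regime_grid"`, `"test2_bias"` or
#'   `"test3_ensemble_size"` (free-form allowed for custom experiments).
#' @param cases List of cases; each case is a list with `description`,
#'   `regime` (a [disturbance_regime()]), `n` (>= 1), `bias` (gC m^-2)
#'   and `k` (years, >= 1).
#' @param replicates_per_case Repeated runs per case (>= 1); rows carry a
#'   `replicate` column.
#' @param seed Experiment seed.
#' @param output_dir Optional directory: results CSV (and per-case
#'   surface JSON) are written there.
#' @param estimator An [estimator_config()] template (its seed is
#'   replaced per case).
#' @param noise A [noise_model()] template for the synthetic truth (its
#'   bias is replaced per case).
#' @param growth,spinup Growth model and spin-up used for the synthetic
#'   truth.
#' @return An object of class `"experiment_spec"`.
#' @export
experiment_spec <- function(test_id, cases, replicates_per_case = 1,
                            seed = 1, output_dir = NULL,
                            estimator = estimator_config(),
                            noise = noise_model(),
                            growth = growth_model(),
                            spinup = spin_up_config()) {
  if (!is.character(test_id) || length(test_id) != 1L)
    .stopf("`test_id` must be a single string")
  if (!is.list(cases) || length(cases) < 1L)
    .stopf("`cases` must be a non-empty list")
  for (cs in cases) {
    .check_regime(cs$regime, "case regime")
    .check_count(cs$n, "case n")
    .check_number(cs$bias, "case bias")
    .check_count(cs$k, "case k")
  }
  .check_count(replicates_per_case, "replicates_per_case")
  .check_number(seed, "seed")
  .check_estimator_config(estimator, "estimator")
  .check_noise_model(noise)
  .check_growth_model(growth, "growth")
  if (!inherits(spinup, "spin_up_config"))
    .stopf("`spinup` must be a spin_up_config object")
  structure(list(test_id = test_id, cases = cases,
                 replicates_per_case = as.integer(replicates_per_case),
                 seed = seed, output_dir = output_dir,
                 estimator = estimator, noise = noise, growth = growth,
                 spinup = spinup),
            class = "experiment_spec")
}

# Content-based case seed: equal cases get equal seeds under one spec
# seed, regardless of their position in the case list.
.case_seed <- function(seed, e_p, e_i, n, bias, k, replicate, salt = 0) {
  v <- c(round(seed), round(e_p * 1e6), round(e_i * 1e6), n,
         round(bias * 1e3), k, replicate, salt)
  h <- 0
  for (x in v) h <- (h * 31 + (x %% 1000003) + 1000003) %% 2147483629
  as.integer(h + 1)
}

.default_case <- function(description, regime, n = 1600, bias = 0, k = 4) {
  list(description = description, regime = regime, n = n, bias = bias,
       k = k)
}

# Simulate one synthetic truth pair for a case: spin-up, one plain model
# year (the first map is taken at the end of year 1; the regime acts only
# during the k separation years), then k disturbed years.
.simulate_case_pair <- function(case, spec, truth_seed) {
  set.seed(truth_seed)
  spin_cfg <- spec$spinup
  spin_cfg$seed <- NULL
  base <- spin_up(case$n, spec$growth, spin_cfg)
  model <- attr(base, "model")
  yr1 <- step_state(base$values, model, disturbance_regime(0, 0),
                    years = 1)
  t1 <- biomass_ensemble(yr1$biomass, base$pixel_edge,
                         base$time_index + 1)
  attr(t1, "model") <- model
  ns <- spec$noise
  ns$bias <- case$bias
  simulate_pair(t1, model, case$regime, ns,
                separation_years = case$k, bias_on = "t1")
}

#' Run an OSSE experiment
#'
#' Executes every (case, replicate) of the spec: synthetic truth
#' generation, estimation, and one results row per run mirroring a
#' validation-table layout (truth columns plus estimated max/min/range of
#' E_I, E_P and E_M).
#'
#' @param spec An [experiment_spec()].
#' @return A data frame with columns `test_id`, `description`,
#'   `replicate`, `n`, `side_m` (side of the square area covered),
#'   `bias`, `separation_years`, `actual_e_i`, `actual_e_p`,
#'   `actual_e_m`, and `est_{ei,ep,em}_{max,min,range}`. Attribute
#'   `"fits"` holds the underlying `regime_fit` objects.
#' @export
run_experiment <- function(spec) {
  if (!inherits(spec, "experiment_spec"))
    .stopf("`spec` must be an experiment_spec object")
  rows <- list()
  fits <- list()
  ridx <- 0L
  for (case in spec$cases) {
    for (rep in seq_len(spec$replicates_per_case)) {
      r <- case$regime
      truth_seed <- .case_seed(spec$seed, r$e_p, r$e_i, case$n, case$bias,
                               case$k, rep, salt = 1)
      est_seed <- .case_seed(spec$seed, r$e_p, r$e_i, case$n, case$bias,
                             case$k, rep, salt = 2)
      pair <- .simulate_case_pair(case, spec, truth_seed)
      cfg <- spec$estimator
      cfg$seed <- est_seed
      fit <- estimate_regime(pair, cfg)
      s <- fit$summaries
      ridx <- ridx + 1L
      rows[[ridx]] <- data.frame(
        test_id = spec$test_id, description = case$description,
        replicate = rep, n = case$n,
        side_m = ensemble_side_m(case$n),
        bias = case$bias, separation_years = case$k,
        actual_e_i = r$e_i, actual_e_p = r$e_p,
        actual_e_m = expected_mean_loss(r),
        est_ei_max = s["E_I", "max"], est_ei_min = s["E_I", "min"],
        est_ei_range = s["E_I", "range"],
        est_ep_max = s["E_P", "max"], est_ep_min = s["E_P", "min"],
        est_ep_range = s["E_P", "range"],
        est_em_max = s["E_M", "max"], est_em_min = s["E_M", "min"],
        est_em_range = s["E_M", "range"],
        stringsAsFactors = FALSE)
      fits[[ridx]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  if (!is.null(spec$output_dir)) {
    dir.create(spec$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_csv(out, file.path(spec$output_dir,
                                     paste0(spec$test_id, "_results.csv")))
    for (i in seq_along(fits))
      write_surface_json(fits[[i]],
                         file.path(spec$output_dir,
                                   sprintf("%s_case%02d_surface.json",
                                           spec$test_id, i)))
  }
  out
}

#' Default spec for the regime-recovery experiment (test 1)
#'
#' Nine cases at n = 1600 pixels and a 4-year map separation: mean annual
#' loss E_M in \{0.018, 0.045, 0.090, 0.180\}, each realised as a
#' high-intensity regime (E_I = 0.9, few pixels hit hard) and a
#' low-intensity regime (E_P = 0.9, most pixels lightly disturbed), plus
#' the no-disturbance case.
#'
#' @param seed Experiment seed.
#' @param n Ensemble size.
#' @param ... Passed on to [experiment_spec()].
#' @return An [experiment_spec()].
#' @export
test1_spec <- function(seed = 1, n = 1600, ...) {
  lvl <- c(0.02, 0.05, 0.10, 0.20)   # E_M = 0.9 * lvl
  cases <- list()
  for (x in lvl)
    cases[[length(cases) + 1L]] <- .default_case(
      sprintf("High intensity, E_M = %.3f", 0.9 * x),
      disturbance_regime(e_p = x, e_i = 0.9), n = n)
  for (x in lvl)
    cases[[length(cases) + 1L]] <- .default_case(
      sprintf("Low intensity, E_M = %.3f", 0.9 * x),
      disturbance_regime(e_p = 0.9, e_i = x), n = n)
  cases[[length(cases) + 1L]] <- .default_case(
    "No disturbance", disturbance_regime(0, 0), n = n)
  experiment_spec("test1_regime_grid", cases, seed = seed, ...)
}

#' Default spec for the observation-bias experiment (test 2)
#'
#' Six cases: first-map biases of -160, 0 and +160 gC m^-2 crossed with
#' the high-intensity (E_I = 0.9, E_P = 0.05) and low-intensity
#' (E_I = 0.05, E_P = 0.9) regimes, both with E_M = 0.045, at n = 1600.
#'
#' @inheritParams test1_spec
#' @return An [experiment_spec()].
#' @export
test2_spec <- function(seed = 1, n = 1600, ...) {
  cases <- list()
  for (b in c(-160, 0, 160)) {
    cases[[length(cases) + 1L]] <- .default_case(
      sprintf("High intensity, bias = %g gC m^-2", b),
      disturbance_regime(e_p = 0.05, e_i = 0.9), n = n, bias = b)
    cases[[length(cases) + 1L]] <- .default_case(
      sprintf("Low intensity, bias = %g gC m^-2", b),
      disturbance_regime(e_p = 0.9, e_i = 0.05), n = n, bias = b)
  }
  experiment_spec("test2_bias", cases, seed = seed, ...)
}

#' Default spec for the ensemble-size experiment (test 3)
#'
#' Four cases at the low-intensity regime (E_I = 0.05, E_P = 0.9,
#' E_M = 0.045) with n = 6400, 1600, 400 and 100 pixels — square areas of
#' 2000, 1000, 500 and 250 m on a side at 25 m pixels.
#'
#' @inheritParams test1_spec
#' @return An [experiment_spec()].
#' @export
test3_spec <- function(seed = 1, ...) {
  cases <- lapply(c(6400, 1600, 400, 100), function(n)
    .default_case(sprintf("Area %g x %g m", ensemble_side_m(n),
                          ensemble_side_m(n)),
                  disturbance_regime(e_p = 0.9, e_i = 0.05), n = n))
  experiment_spec("test3_ensemble_size", cases, seed = seed, ...)
}

#' Run the three OSSE validation experiments
#'
#' Convenience wrappers running [run_experiment()] on the default specs.
#'
#' @param spec An [experiment_spec()]; defaults to the canonical spec for
#'   the test.
#' @return The results data frame (see [run_experiment()]).
#' @export
run_test1 <- function(spec = test1_spec()) {
  run_experiment(spec)
}

#' @rdname run_test1
#' @export
run_test2 <- function(spec = test2_spec()) {
  run_experiment(spec)
}

#' @rdname run_test1
#' @export
run_test3 <- function(spec = test3_spec()) {
  run_experiment(spec)
}
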