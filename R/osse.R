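#' A pixel ensemble of biomass values
#'
#' The unit of analysis: a vector of per-pixel aboveground biomass carbon
#' densities (gC m^-2) for n satellite pixels sharing one disturbance
#' regime. Pixels need not be contiguous. True-state ensembles are
#' non-negative; observed ensembles may contain negative values because
#' additive observation noise is never clipped.
#'
#' @param values Numeric vector of per-pixel biomass, gC m^-2; finite,
#'   length >= 1.
#' @param pixel_edge Pixel edge length in metres (default 25, typical of
#'   ALOS PALSAR biomass products).
#' @param time_index Years since simulation start (bookkeeping only).
#' @return An object of class `"biomass_ensemble"`.
#' @export
biomass_ensemble <- function(values, pixel_edge = 25, time_index = 0) {
  if (!is.numeric(values) || length(values) < 1L)
    .stopf("`values` must be a non-empty numeric vector")
  if (anyNA(values) || any(!is.finite(values)))
    .stopf("`values` must be finite throughout")
  .check_number(pixel_edge, "pixel_edge")
  if (pixel_edge <= 0) .stopf("`pixel_edge` must be > 0")
  .check_number(time_index, "time_index")
  structure(list(values = as.numeric(values), pixel_edge = pixel_edge,
                 time_index = time_index),
            class = "biomass_ensemble")
}

#' @export
print.biomass_ensemble <- function(x, ...) {
  cat(sprintf(
    "Biomass ensemble: n = %d pixels (%g m edge), mean = %.1f, sd = %.1f gC m^-2\n",
    length(x$values), x$pixel_edge, mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' Side length of the square area covered by an ensemble
#'
#' For n pixels of edge e, `sqrt(n) * e` metres: 1600 pixels of 25 m cover
#' a 1000 x 1000 m square, 6400 cover 2000 x 2000 m, 400 cover 500 x 500 m.
#'
#' @param n Number of pixels.
#' @param pixel_edge Pixel edge length, metres.
#' @return Side length in metres.
#' @export
ensemble_side_m <- function(n, pixel_edge = 25) {
  .check_count(n, "n")
  .check_number(pixel_edge, "pixel_edge")
  sqrt(n) * pixel_edge
}

#' Observation noise model for biomass maps
#'
#' Describes the per-pixel random error of a remotely sensed biomass map,
#' plus an optional systematic bias applied to one observation date.
#' Two error domains are supported:
#' * `"biomass_linear"`: additive Gaussian noise with standard deviation
#'   `sd` gC m^-2 (errors reported as normal in the biomass domain);
#' * `"dB"`: Gaussian noise of `sd` dB on `10*log10(biomass)`,
#'   back-transformed — multiplicative, asymmetric (log-normal) error on
#'   the linear scale, as assumed by some SAR retrieval studies.
#'
#' The default linear-domain sd of 800 gC m^-2 is a placeholder of the
#' right order for 25 m SAR biomass pixels, not a published value; set it
#' from the error characterisation of the maps in hand.
#'
#' @param sd Noise standard deviation, non-negative: gC m^-2 (linear) or
#'   dB (dB domain).
#' @param domain `"biomass_linear"` or `"dB"`.
#' @param bias Additive systematic error, gC m^-2, applied only when an
#'   observation is flagged as the biased date.
#' @param floor dB domain only: positive biomass floor substituted before
#'   taking logs (required if any pixel can be 0).
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sd = 800, domain = c("biomass_linear", "dB"),
                        bias = 0, floor = NULL) {
  domain <- match.arg(domain)
  .check_number(sd, "sd", lower = 0)
  .check_number(bias, "bias")
  .check_number(floor, "floor", allow_null = TRUE)
  if (!is.null(floor) && floor <= 0) .stopf("`floor` must be > 0")
  structure(list(sd = sd, domain = domain, bias = bias, floor = floor),
            class = "noise_model")
}

.check_noise_model <- function(x, name = "noise") {
  if (!inherits(x, "noise_model"))
    .stopf("`%s` must be a noise_model object", name)
  invisible(x)
}

#' Generate a synthetic baseline biomass ensemble
#'
#' Draws a unimodal, right-skewed non-negative ensemble emulating the
#' pixel biomass distribution of a dry-woodland SAR biomass map. This is a
#' synthetic stand-in for a real calibration target; the default
#' (gamma, mean 2500 gC m^-2, cv 0.5) is a plausible miombo distribution,
#' not a published one, and is fully configurable.
#'
#' @param n Number of pixels.
#' @param mean Target mean biomass, gC m^-2 (> 0).
#' @param cv Coefficient of variation (> 0).
#' @param shape Distribution family: `"gamma"`, `"lognormal"` or
#'   `"truncated_normal"` (normal with negative draws resampled).
#' @param pixel_edge Pixel edge length, metres.
#' @return A [biomass_ensemble()].
#' @export
generate_baseline <- function(n, mean = 2500, cv = 0.5,
                              shape = c("gamma", "lognormal",
                                        "truncated_normal"),
                              pixel_edge = 25) {
  .check_count(n, "n")
  .check_number(mean, "mean")
  if (mean <= 0) .stopf("`mean` must be > 0")
  .check_number(cv, "cv")
  if (cv <= 0) .stopf("`cv` must be > 0")
  if (is.character(shape) && length(shape) == 1L &&
      !shape %in% c("gamma", "lognormal", "truncated_normal"))
    .stopf("unsupported baseline shape: %s", shape)
  shape <- match.arg(shape)
  values <- switch(shape,
    gamma = {
      k <- 1 / cv^2
      stats::rgamma(n, shape = k, scale = mean * cv^2)
    },
    lognormal = {
      s2 <- log(1 + cv^2)
      stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
    },
    truncated_normal = {
      # shift the pre-truncation location so the zero-truncated mean
      # equals the target (truncation alone would inflate it)
      sigma <- mean * cv
      mu <- stats::uniroot(function(m)
        m + sigma * stats::dnorm(m / sigma) / stats::pnorm(m / sigma) - mean,
        c(-10 * sigma, mean), tol = 1e-10)$root
      out <- stats::rnorm(n, mu, sigma)
      while (any(out < 0))
        out[out < 0] <- stats::rnorm(sum(out < 0), mu, sigma)
      out
    })
  biomass_ensemble(values, pixel_edge = pixel_edge)
}

#' Apply one year of stochastic disturbance to an ensemble
#'
#' For each pixel independently one uniform draw u is taken; the pixel is
#' disturbed iff u < e_p, in which case its biomass becomes
#' `(1 - e_i) * B`. Undisturbed pixels are unchanged.
#'
#' @param biomass Non-negative biomass vector, gC m^-2 (a plain vector or
#'   a [biomass_ensemble()]).
#' @param regime A [disturbance_regime()].
#' @return A list with `biomass` (disturbed vector) and `mask` (logical
#'   vector, TRUE where disturbed).
#' @export
apply_disturbance <- function(biomass, regime) {
  if (inherits(biomass, "biomass_ensemble")) biomass <- biomass$values
  .check_biomass_vector(biomass, "biomass")
  .check_regime(regime)
  u <- stats::runif(length(biomass))
  mask <- u < regime$e_p
  out <- biomass * (1 - regime$e_i * mask)
  list(biomass = out, mask = mask)
}

#' Observe an ensemble through a noise model
#'
#' Adds per-pixel observation error to a true biomass state. In the linear
#' domain the observation is `B + bias*[apply_bias] + N(0, sd)`; in the dB
#' domain `10*log10(B)` is perturbed by `N(0, sd_dB)` and back-transformed
#' before the bias is added. Negative observed values are retained, never
#' clipped: the estimator works on the difference distribution and
#' clipping would skew it.
#'
#' @param biomass Non-negative true biomass vector or [biomass_ensemble()].
#' @param noise A [noise_model()].
#' @param apply_bias Whether this observation date receives the systematic
#'   bias.
#' @return Numeric vector of observed biomass, gC m^-2.
#' @export
observe <- function(biomass, noise, apply_bias = FALSE) {
  if (inherits(biomass, "biomass_ensemble")) biomass <- biomass$values
  .check_biomass_vector(biomass, "biomass")
  .check_noise_model(noise)
  n <- length(biomass)
  bias <- if (isTRUE(apply_bias)) noise$bias else 0
  if (noise$domain == "biomass_linear") {
    return(biomass + bias + stats::rnorm(n, 0, noise$sd))
  }
  # dB domain: Gaussian on 10*log10(B)
  b <- biomass
  if (any(b <= 0)) {
    if (is.null(noise$floor))
      .stopf("dB-domain noise requires strictly positive biomass or a configured `floor`")
    b <- pmax(b, noise$floor)
  }
  db <- 10 * log10(b) + stats::rnorm(n, 0, noise$sd)
  10^(db / 10) + bias
}

#' Bundle two observations of the same pixels
#'
#' @param obs_t1,obs_t2 [biomass_ensemble()] objects (observed values) of
#'   equal length.
#' @param separation_years Years between the observations (k >= 1).
#' @param truth Optional list retaining the generating truth for OSSE
#'   scoring (true states, regime, disturbance masks, seed).
#' @return An object of class `"observation_pair"`.
#' @export
observation_pair <- function(obs_t1, obs_t2, separation_years, truth = NULL) {
  if (!inherits(obs_t1, "biomass_ensemble") ||
      !inherits(obs_t2, "biomass_ensemble"))
    .stopf("`obs_t1` and `obs_t2` must be biomass_ensemble objects")
  if (length(obs_t1$values) != length(obs_t2$values))
    .stopf("observations must cover the same pixels (lengths %d vs %d)",
           length(obs_t1$values), length(obs_t2$values))
  separation_years <- .check_count(separation_years, "separation_years")
  structure(list(obs_t1 = obs_t1, obs_t2 = obs_t2,
                 separation_years = separation_years, truth = truth),
            class = "observation_pair")
}

#' @export
print.observation_pair <- function(x, ...) {
  d <- delta_distribution(x)
  cat(sprintf(
    "Observation pair: n = %d pixels, %d year(s) apart; mean dO = %.1f gC m^-2%s\n",
    length(x$obs_t1$values), x$separation_years, mean(d),
    if (is.null(x$truth)) "" else " (truth retained)"))
  invisible(x)
}

#' Per-pixel biomass change between the two observation dates
#'
#' The estimator's sole data summary: the elementwise, order-preserving
#' difference dO = O(t2) - O(t1).
#'
#' @param pair An [observation_pair()].
#' @return Numeric vector, gC m^-2.
#' @export
delta_distribution <- function(pair) {
  if (!inherits(pair, "observation_pair"))
    .stopf("`pair` must be an observation_pair object")
  pair$obs_t2$values - pair$obs_t1$values
}

#' Simulate a noisy observation pair under a known regime
#'
#' The OSSE forward model: the baseline is the true state at the first
#' observation date; it is observed through the noise model, advanced
#' `separation_years` annual steps of growth-then-disturbance, and
#' observed again with independent noise. The systematic bias, if any, is
#' applied to the date named by `bias_on` (the first date by default,
#' matching how map bias is usually probed).
#'
#' @param baseline A [biomass_ensemble()] true state at t1 (e.g. from
#'   [spin_up()] or [generate_baseline()]).
#' @param model A [growth_model()]. If the baseline carries a per-pixel
#'   model attribute (as [spin_up()] output does) that model is used.
#' @param regime The true [disturbance_regime()].
#' @param noise A [noise_model()].
#' @param separation_years k >= 1.
#' @param bias_on Which observation receives the bias: `"t1"`, `"t2"` or
#'   `"none"`.
#' @return An [observation_pair()] with `truth` retained (true states at
#'   both dates, the regime, and per-year disturbance masks).
#' @export
simulate_pair <- function(baseline, model, regime, noise,
                          separation_years = 1,
                          bias_on = c("t1", "t2", "none")) {
  if (!inherits(baseline, "biomass_ensemble"))
    .stopf("`baseline` must be a biomass_ensemble object")
  bias_on <- match.arg(bias_on)
  attr_model <- attr(baseline, "model")
  if (inherits(attr_model, "growth_model")) model <- attr_model
  .check_growth_model(model)
  .check_regime(regime)
  .check_noise_model(noise)
  separation_years <- .check_count(separation_years, "separation_years")

  o1 <- observe(baseline$values, noise, apply_bias = bias_on == "t1")
  st <- step_state(baseline$values, model, regime, years = separation_years)
  o2 <- observe(st$biomass, noise, apply_bias = bias_on == "t2")

  t2_index <- baseline$time_index + separation_years
  observation_pair(
    obs_t1 = biomass_ensemble(o1, baseline$pixel_edge, baseline$time_index),
    obs_t2 = biomass_ensemble(o2, baseline$pixel_edge, t2_index),
    separation_years = separation_years,
    truth = list(state_t1 = baseline$values, state_t2 = st$biomass,
                 regime = regime, masks = st$masks))
}
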