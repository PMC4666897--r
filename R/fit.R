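#' Estimate a disturbance regime from an observation pair
#'
#' The main fitting function: given two co-registered noisy biomass maps
#' of the same pixel ensemble, recovers the disturbance regime (E_P, E_I)
#' and the derived mean annual fractional loss E_M by simulation-based
#' maximum likelihood. The per-pixel change distribution dO = O(t2) -
#' O(t1) is compared with simulated change distributions over a regular
#' grid of candidate regimes; the normalised likelihood surface yields a
#' maximum-likelihood regime and a 95% cumulative-likelihood credible
#' region, from which min/max/range summaries of E_P, E_I and E_M are
#' read.
#'
#' @param pair An [observation_pair()] (its `separation_years` sets the
#'   number of annual simulation steps between the two dates).
#' @param config An [estimator_config()].
#' @param level Credible-region coverage (defaults to `config$level`).
#' @return An object of class `"regime_fit"` with components `argmax`
#'   (the most likely [disturbance_regime()]), `surface`, `region`,
#'   `summaries` (min/max/range for E_P, E_I, E_M), `delta` (the observed
#'   dO vector), `n`, `separation_years`, `config` and, when the pair was
#'   simulated, the generating `truth` regime.
#' @examples
#' \donttest{
#' set.seed(1)
#' base <- spin_up(400, growth_model(), spin_up_config())
#' pair <- simulate_pair(base, growth_model(),
#'                       disturbance_regime(0.05, 0.9), noise_model(),
#'                       separation_years = 4)
#' fit <- estimate_regime(pair, estimator_config(grid_step = 0.1,
#'                                               replicates = 5, seed = 7))
#' fit
#' }
#' @export
estimate_regime <- function(pair, config = estimator_config(),
                            level = config$level) {
  if (!inherits(pair, "observation_pair"))
    .stopf("`pair` must be an observation_pair object")
  .check_estimator_config(config)
  delta <- delta_distribution(pair)
  surface <- likelihood_surface(delta, config, pair$separation_years,
                                obs_t1 = pair$obs_t1$values)
  region <- credible_region(surface, level)
  truth_regime <- if (!is.null(pair$truth)) pair$truth$regime else NULL
  structure(list(argmax = arg_max_regime(surface), surface = surface,
                 region = region, summaries = region$summaries,
                 delta = delta, n = length(delta),
                 separation_years = pair$separation_years,
                 config = config, truth = truth_regime,
                 call = match.call()),
            class = "regime_fit")
}

#' @export
print.regime_fit <- function(x, ...) {
  cat("Disturbance-regime fit (simulation-based maximum likelihood)\n")
  cat(sprintf("  n = %d pixels, %d year(s) between maps, %d x %d grid\n",
              x$n, x$separation_years,
              length(x$surface$e_p_axis), length(x$surface$e_i_axis)))
  cat(sprintf("  Most likely regime: E_P = %g, E_I = %g (E_M = %g)\n",
              x$argmax$e_p, x$argmax$e_i, expected_mean_loss(x$argmax)))
  cat(sprintf("  %.0f%% region summaries (min/max/range):\n",
              100 * x$region$level))
  print(round(x$summaries, 4))
  invisible(x)
}

#' @export
coef.regime_fit <- function(object, ...) {
  c(E_P = object$argmax$e_p, E_I = object$argmax$e_i,
    E_M = expected_mean_loss(object$argmax))
}

#' @export
confint.regime_fit <- function(object, parm = c("E_P", "E_I", "E_M"),
                               level = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  reg <- object$region
  if (!is.null(level) && !isTRUE(all.equal(level, reg$level)))
    reg <- credible_region(object$surface, level)
  ci <- reg$summaries[parm, c("min", "max"), drop = FALSE]
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - reg$level) / 2,
                                             1 - (1 - reg$level) / 2))
  ci
}

#' @export
summary.regime_fit <- function(object, ...) {
  out <- list(argmax = coef(object), summaries = object$summaries,
              level = object$region$level,
              n_cells = nrow(object$region$cells),
              n = object$n, separation_years = object$separation_years,
              delta_mean = mean(object$delta),
              delta_sd = stats::sd(object$delta),
              truth = object$truth)
  class(out) <- "summary.regime_fit"
  out
}

#' @export
print.summary.regime_fit <- function(x, ...) {
  cat("Disturbance-regime fit\n")
  cat(sprintf("  Observed dO: n = %d, mean = %.1f, sd = %.1f gC m^-2 over %d year(s)\n",
              x$n, x$delta_mean, x$delta_sd, x$separation_years))
  cat(sprintf("  Most likely: E_P = %g, E_I = %g, E_M = %g\n",
              x$argmax[["E_P"]], x$argmax[["E_I"]], x$argmax[["E_M"]]))
  cat(sprintf("  %.0f%% cumulative-likelihood region (%d cells):\n",
              100 * x$level, x$n_cells))
  print(round(x$summaries, 4))
  if (!is.null(x$truth))
    cat(sprintf("  Generating truth: E_P = %g, E_I = %g, E_M = %g\n",
                x$truth$e_p, x$truth$e_i, expected_mean_loss(x$truth)))
  invisible(x)
}

#' Plot a fitted likelihood surface and credible region
#'
#' Displays the normalised likelihood over the (E_P, E_I) grid, outlines
#' the credible-region cells, and marks the maximum-likelihood regime
#' (and the generating truth, if known, as a cross).
#'
#' @param x A `regime_fit` object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.regime_fit <- function(x, ...) {
  s <- x$surface
  graphics::image(s$e_p_axis, s$e_i_axis, s$lik_norm,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = expression(E[P]), ylab = expression(E[I]),
                  main = sprintf("Likelihood surface (%.0f%% region outlined)",
                                 100 * x$region$level), ...)
  graphics::points(x$region$cells$e_p, x$region$cells$e_i,
                   pch = 22, cex = 0.6, col = "grey30")
  graphics::points(x$argmax$e_p, x$argmax$e_i, pch = 19, col = "blue")
  if (!is.null(x$truth))
    graphics::points(x$truth$e_p, x$truth$e_i, pch = 3, cex = 1.6,
                     lwd = 2, col = "black")
  invisible(x)
}

#' Does a credible region contain a given regime?
#'
#' A regime is contained when some region cell lies within half a grid
#' step of it in both coordinates (i.e. the regime falls in that cell).
#'
#' @param region A [credible_region()].
#' @param regime A [disturbance_regime()].
#' @param grid_step The grid step of the surface the region came from.
#' @return Logical scalar.
#' @export
region_contains <- function(region, regime, grid_step = 0.025) {
  if (!inherits(region, "credible_region"))
    .stopf("`region` must be a credible_region object")
  .check_regime(regime)
  half <- grid_step / 2 + 1e-9
  any(abs(region$cells$e_p - regime$e_p) <= half &
      abs(region$cells$e_i - regime$e_i) <= half)
}
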