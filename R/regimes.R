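#' Define a forest disturbance regime
#'
#' A disturbance regime describes how an ensemble of pixels loses biomass:
#' each year every pixel is disturbed independently with probability `e_p`,
#' and a disturbed pixel loses the fraction `e_i` of its biomass. The
#' ensemble mean fractional biomass loss per year is the product
#' `e_m = e_p * e_i`, which is exposed only as a derived quantity (see
#' [expected_mean_loss()]) so it can never disagree with its factors.
#'
#' @param e_p Probability of disturbance per pixel per year, in \[0, 1\].
#' @param e_i Fraction of biomass lost per disturbance event, in \[0, 1\].
#'
#' @return An object of class `"disturbance_regime"`: a list with elements
#'   `e_p` and `e_i`.
#'
#' @examples
#' r <- disturbance_regime(e_p = 0.05, e_i = 0.2)
#' expected_mean_loss(r)   # 0.01: a 1% annual reduction in ensemble biomass
#' classify_regime(r)      # "degradation"
#' @export
disturbance_regime <- function(e_p, e_i) {
  .check_number(e_p, "e_p", 0, 1)
  .check_number(e_i, "e_i", 0, 1)
  structure(list(e_p = as.numeric(e_p), e_i = as.numeric(e_i)),
            class = "disturbance_regime")
}

.check_regime <- function(x, name = "regime") {
  if (!inherits(x, "disturbance_regime"))
    .stopf("`%s` must be a disturbance_regime object", name)
  invisible(x)
}

#' Expected mean fractional biomass loss per year
#'
#' Returns `e_m = e_p * e_i`, the annual mean fractional biomass loss for
#' an ensemble under the regime. The identity is exact for a single year;
#' over a gap of k years losses compound as `(1 - e_p * e_i)^k` (handled by
#' the simulator, not here).
#'
#' @param regime A [disturbance_regime()].
#' @return The dimensionless annual mean fractional loss, in \[0, 1\].
#' @examples
#' expected_mean_loss(disturbance_regime(0.02, 0.9))  # 0.018
#' @export
expected_mean_loss <- function(regime) {
  .check_regime(regime)
  regime$e_p * regime$e_i
}

#' Annual biomass loss rate as a percentage
#'
#' @param regime A [disturbance_regime()].
#' @return `100 * e_p * e_i`, percent per year.
#' @examples
#' annual_loss_percent(disturbance_regime(0.05, 0.9))  # 4.5
#' @export
annual_loss_percent <- function(regime) {
  100 * expected_mean_loss(regime)
}

#' Classify a regime within the disturbance parameter space
#'
#' Partitions the (E_P, E_I) unit square into named regions:
#' * `no_disturbance`: `e_m = 0` (either factor zero);
#' * `total_deforestation`: `e_p = 1` and `e_i = 1` (everything cleared);
#' * `partial_deforestation`: `e_i = 1` with `0 < e_p < 1` (disturbed
#'   pixels are cleared completely, but only some are disturbed);
#' * `degradation`: everything else (`0 < e_i < 1`), including the
#'   boundary `e_p = 1, e_i < 1` where every pixel loses a fraction but
#'   none is deforested.
#'
#' The labels are mutually exclusive and exhaustive over the unit square.
#'
#' @param regime A [disturbance_regime()].
#' @return A single character label.
#' @examples
#' classify_regime(disturbance_regime(1, 1))      # "total_deforestation"
#' classify_regime(disturbance_regime(0.5, 1))    # "partial_deforestation"
#' classify_regime(disturbance_regime(0.9, 0.05)) # "degradation"
#' @export
classify_regime <- function(regime) {
  .check_regime(regime)
  if (regime$e_p == 0 || regime$e_i == 0) return("no_disturbance")
  if (regime$e_i == 1) {
    if (regime$e_p == 1) return("total_deforestation")
    return("partial_deforestation")
  }
  "degradation"
}

#' @export
print.disturbance_regime <- function(x, ...) {
  cat(sprintf(
    "Disturbance regime: E_P = %g, E_I = %g  (E_M = %g, %s)\n",
    x$e_p, x$e_i, expected_mean_loss(x), classify_regime(x)))
  invisible(x)
}

#' @export
format.disturbance_regime <- function(x, ...) {
  sprintf("(E_P=%g, E_I=%g)", x$e_p, x$e_i)
}

#' Serialize or restore a regime as plain key-value entries
#'
#' Used by experiment configs and file sidecars.
#'
#' @param regime A [disturbance_regime()].
#' @param x A named list (or vector) with entries `e_p` and `e_i`.
#' @return `regime_to_list()` returns a named list; `regime_from_list()`
#'   returns a [disturbance_regime()].
#' @export
regime_to_list <- function(regime) {
  .check_regime(regime)
  list(e_p = regime$e_p, e_i = regime$e_i)
}

#' @rdname regime_to_list
#' @export
regime_from_list <- function(x) {
  if (is.null(x$e_p) || is.null(x$e_i))
    .stopf("regime entries must provide `e_p` and `e_i`")
  disturbance_regime(as.numeric(x$e_p), as.numeric(x$e_i))
}
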