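# forestdist

Estimating the intensity of forest disturbance from two successive
remotely sensed biomass maps.

## The problem

Satellites map deforestation well, but an average biomass loss rate for a
region cannot say whether that loss came from clearing a few locations
completely or from lightly disturbing a wide area — regimes with very
different causes and management implications. Per-pixel change detection
cannot resolve this either, because radar-derived biomass maps carry large
per-pixel random error.

`forestdist` implements a framework that works on an *ensemble* of n
pixels assumed to share one disturbance regime. The regime is described by
two factors:

* **E_P** — the probability that a pixel is disturbed in a year;
* **E_I** — the fraction of biomass a disturbed pixel loses;

and the ensemble mean fractional biomass loss per year is their product,

```
E_M = E_P · E_I
```

with E_M, E_P, E_I all in [0, 1]. Deforestation is the special case
E_I = 1 (complete loss on disturbed pixels); degradation is 0 < E_I < 1,
possibly widespread (high E_P). For example E_P = 0.05 and E_I = 0.2 gives
E_M = 0.01: a 1 % annual loss of ensemble biomass.

Given two co-registered biomass maps k ≥ 1 years apart, the package
recovers (E_P, E_I) — and the derived E_M — by simulation-based maximum
likelihood: for every candidate regime on a grid over [0, 1]², it spins up
a synthetic pixel ensemble matching the first map's biomass distribution,
applies annual growth and stochastic disturbance (one Bernoulli(E_P) draw
per pixel per year; disturbed pixels keep the fraction 1 − E_I), adds
observation noise at both dates, and scores the candidate by the
multinomial likelihood of the observed per-pixel change distribution
ΔO = O(t2) − O(t1) under the simulated change distribution. The cells
accumulating the first 95 % of normalised likelihood form a credible
region from which min/max/range summaries of E_P, E_I and E_M are read.

The package also ships the full observing-system simulation experiment
(OSSE) machinery used to validate the estimator against known synthetic
truths: an annual saturating growth model with ensemble spin-up, the
stochastic disturbance operator, linear- and dB-domain noise models with
optional systematic bias, and three canonical experiments (regime
recovery, map bias, ensemble size).

## Worked example

Simulate a high-intensity truth (E_I = 0.9, E_P = 0.05, so E_M = 0.045)
over a 4-year gap with heavy map noise, then recover it:

```r
library(forestdist)

set.seed(42)
base  <- spin_up(1600, growth_model(), spin_up_config())  # ~miombo ensemble
model <- attr(base, "model")
yr1   <- step_state(base$values, model, disturbance_regime(0, 0), 1)
t1    <- biomass_ensemble(yr1$biomass, 25, 1); attr(t1, "model") <- model

truth <- disturbance_regime(e_p = 0.05, e_i = 0.9)
pair  <- simulate_pair(t1, model, truth, noise_model(sd = 800),
                       separation_years = 4)

fit <- estimate_regime(pair, estimator_config(seed = 42))
summary(fit)
```

```
Disturbance-regime fit
  Observed dO: n = 1600, mean = -400.4, sd = 1444.8 gC m^-2 over 4 year(s)
  Most likely: E_P = 0.075, E_I = 0.675, E_M = 0.050625
  95% cumulative-likelihood region (12 cells):
       min    max  range
E_P 0.0500 0.0750 0.0250
E_I 0.6250 0.9000 0.2750
E_M 0.0388 0.0563 0.0175
  Generating truth: E_P = 0.05, E_I = 0.9, E_M = 0.045
```

Reading the output: the ensemble lost on average 400 gC m⁻² over the four
years, but individual pixel changes are dominated by noise (sd ≈ 1445).
The 95 % region still pins the regime to a *high-intensity* corner —
few pixels disturbed (E_P ≤ 0.075), each losing most of its biomass
(E_I ≥ 0.63) — and brackets all three true values. E_M is the tightest
constrained quantity, the factors less so; `plot(fit)` shows the full
likelihood surface with the region outlined and the truth crossed.

The three validation experiments are one call each and return one table
row per case (truth columns plus estimated max/min/range for E_I, E_P,
E_M):

```r
r1 <- run_test1(test1_spec(seed = 1))  # nine regimes at n = 1600, k = 4
r2 <- run_test2(test2_spec(seed = 1))  # map bias -160 / 0 / +160 gC m^-2
r3 <- run_test3(test3_spec(seed = 1))  # n = 6400, 1600, 400, 100
```

A command-line wrapper (installed at `inst/cli/forestdist`) exposes
`simulate`, `estimate` and `test1`–`test3` subcommands over CSV/TIFF maps.

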