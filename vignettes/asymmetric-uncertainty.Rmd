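---
title: "Asymmetric measurement uncertainty from validation precision data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymmetric measurement uncertainty from validation precision data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymuncert)
```

## The problem

A routine analytical result `ym` is usually reported with a symmetric
uncertainty interval `ym ± U`, where `U = k·u(ym)` is the expanded
uncertainty. When the dispersion of results depends on concentration
(heteroscedasticity) this convention becomes internally inconsistent: with
a constant relative standard deviation (RSD) of 35 % and `k = 2`, a result
of 10 yields the interval [3, 17] while a result of 3 yields [0.9, 5.1] —
so 3 is "reasonably attributable" from 10, but not the other way round.
`asymuncert` implements an alternative that derives the uncertainty
interval by inverting a *prediction range* estimated from an in-house
validation study with known concentrations, which restores mutual
consistency and produces intervals that are asymmetric whenever the data
are heteroscedastic.

## Model

A validation study measures samples of known concentration `x` at `m`
levels across `n` blocks (factor-level combinations of a crossed two-level
design, e.g. operator × instrument × storage) with `p` replicates. The
measurement model is a mixed linear model in which every random term has
an absolute (constant) and a relative (proportional) part:

```
Y_ijk = alpha + beta·x_ij
        + A_j^(factors) + B_j^(factors)·x_ij     # sums of per-factor effects
        + A_j^(block)   + B_j^(block)·x_ij
        + a_ijk + b_ijk·x_ij                     # repeatability
```

`alpha` and `beta − 1` are the absolute and relative components of method
bias; `alpha + beta·x` is the *mean curve*. Each factor's effects are
indexed by factor level (shared across all blocks at that level), block
effects by block, repeatability per observation. All effects are zero-mean
with term-specific variances, so the in-house reproducibility variance at
concentration `x` is the variance function

```
sigma^2(x) = C + P·x^2
```

with `C` the sum of all constant components and `P` the sum of all
proportional ones. The relative SD `sigma(x)/x` falls from large values
near zero concentration towards the plateau `sqrt(P)` — the fingerprint of
the constant-plus-proportional structure.

### Estimation

`fit_uncertainty_model()` maximises the restricted likelihood over
standard-deviation parameters, so every variance is non-negative by
construction and boundary estimates come out as exact zeros — validation
data sets routinely pin several components to zero. The marginal
covariance is assembled densely (validation studies have tens of
observations, so dense Cholesky is both simplest and fastest), the
analytic REML gradient is supplied to `L-BFGS-B`, and a short
derivative-free polish guards against stalls on the flat directions that
boundary zeros create. Three starting points (balanced, constant-heavy,
proportional-heavy, all scaled from the OLS residual SD) protect against
local optima; the best restricted likelihood wins. Convergence is assessed
at a relative log-likelihood tolerance of `1e-8` (`tol`), with `max_iter =
500`; the fit involves no randomness. Fixed effects are generalised least
squares at the estimated covariance.

Two estimation caveats are inherent to the design, not to the
implementation:

* with two-level factors each component is estimated from essentially one
  contrast, so *individual* components are noisy and often hit the zero
  boundary; the aggregates `C` and `P` (all that the uncertainty interval
  uses) are much better determined;
* terms whose level partitions coincide (aliased columns of the design)
  are confounded; the fit warns and the likelihood splits the sum
  arbitrarily between them, leaving `C` and `P` unaffected.

No exact-zero thresholding is applied to reported components; tables round
at reporting time (percentages to 1 d.p., SDs to 2 d.p., components to
5 d.p.), full precision is kept internally.

## From prediction range to uncertainty interval

`prediction_range()` turns a fit into the band
`f_{L,U}(y) = alpha + beta·y ∓ k·sigma(y)` that contains a future single
measurement at true concentration `y` with the prediction probability
implied by `k`. For a routine result `ym`, `uncertainty_interval()` solves

```
f_U(yL) = ym      and      f_L(yU) = ym
```

for the lower and upper uncertainty limits: measurands below `yL` would
rarely produce a result as large as `ym`, measurands above `yU` rarely one
as small. The best estimate is the inverse mean curve
`ycorr = (ym − alpha)/beta` — a bias/recovery correction. Both `f_U` and
(when `beta > k·sqrt(P)`) `f_L` are strictly increasing, so the roots are
unique; they are found by geometric bracket growth from `ycorr` plus
`uniroot`, and accepted only if `|f(root) − ym| ≤ 1e-9·max(1, ym)`.
Degenerate geometry is handled by flags, not exceptions: `f_U(0) ≥ ym`
truncates `yL` (and `ycorr`) at zero, and `beta ≤ k·sqrt(P)` means the
lower prediction curve never climbs back to `ym`, so the interval is
unbounded above. Special cases with closed forms:

* constant absolute SD (`P = 0`) and no bias: the interval is exactly
  `ym ± k·sigma` — the symmetric convention is recovered;
* constant RSD (`C = 0`) and no bias:
  `[ym/(1 + k·sigma_rel), ym/(1 − k·sigma_rel)]`
  (`closed_form_interval()`), unbounded above once `k·sigma_rel ≥ 1`;
* variance-stabilising log transform: `[ym/exp(k·sigma), ym·exp(k·sigma)]`
  (`lognormal_interval()`), a milder asymmetry than the normal-theory
  closed form at the same RSD.

With the exact 95 % quantile (`p_pred = 0.95` gives `k = 1.959964`) and
the generative assumptions holding, the asymmetric interval's coverage is
exactly 95 %; the package verifies this by simulation. `k` and `p_pred`
are alternative parameterisations of the same band and are never mixed in
one report; the default is the conventional `k = 2`.

### Bias modes

Reports can apply the mean curve inside the band (`bias = "corrected"`,
the default — the limits then include the recovery correction) or replace
it by the identity (`bias = "none"`). The recommendation to propagate the
*uncertainty of the bias correction* itself is accommodated by adding an
extra constant/proportional component to the profile before building the
range; no formula for it is imposed, and nothing is added by default.

## The simulation engine

`simulate_study()` draws data sets from exactly the model above: factor
effects once per level, block effects once per block, repeatability per
observation, each with its constant and proportional part
(`distribution = "normal"`). The lognormal mode exponentiates additive
log-domain effects around `log(alpha + beta·x)` (all constant components
must be zero there), with no mean-bias adjustment — the simple
back-transform reading. One integer seed expands into deterministic
per-replicate seeds, so experiments are reproducible independently of
replication order, and factor effects are redrawn for every simulated
study (they are random effects, not fixed features of a laboratory).

What the generator deliberately does *not* emulate: outliers and
heavy-tailed errors, drift within blocks, correlation between the constant
and proportional parts of one term (the model treats them as independent —
nothing in the estimation requires it, but the generator draws them
independently), calibration-standard uncertainty, and censoring at the
limit of detection. Passing coverage and recovery tests therefore
demonstrate internal consistency of model + estimator + inversion, not
robustness to those real-data features.

`coverage_experiment()` simulates a routine measurement from the known
truth and checks whether the interval built by a rule contains the true
measurand; `recovery_experiment()` refits every simulated study and
tabulates estimate distributions, counting (never hiding)
non-convergences.

## Numerical and design choices

* **Problem sizes.** The bundled studies have 32 and 48 observations; a
  REML fit takes well under a second. The package's own experiments use
  R = 10000 replicates for coverage (binomial SE ≈ 0.2 %) and R = 200
  refits for parameter recovery on the 8-block design — sizes at which the
  Monte Carlo error is small against the 30 % recovery tolerance discussed
  below.
* **Refit tolerances.** The published variance tables for the two example
  studies were produced by an unspecified variance-component estimator.
  Our REML refit agrees with the published aggregates `C` and `P` to a few
  percent and reproduces the published interval limits to ≈ 0.01 ug/kg in
  the egg study; the documented comparison tolerance is 10 % (0.002
  absolute for near-zero components) on components and 0.05 ug/kg plus
  half a print unit on limits, since tables printed at 1 d.p. can
  themselves sit half a unit from the computed value.
* **Recovery tolerance.** With 8 blocks and two-level factors, individual
  variance components have ~1 degree of freedom each; their estimates hit
  the zero boundary so often that even the *median* estimate of a small
  component can be 0. Recovery is therefore asserted on the aggregates
  `C`, `P`, on `beta`, and on `sigma(x)` inside the calibrated range
  (median within 30 % of truth) — the quantities the uncertainty interval
  actually consumes.
* **Zero and negative handling.** `yL` and `ycorr` are floored at 0 and
  flagged (`truncated_low`), matching how reports print "0.00";
  `unbounded_high` marks intervals without a finite upper limit. Flags are
  carried into report footers rather than raising errors, because both
  situations are legitimate outcomes near the detection limit.
* **CSV dialect.** UTF-8, comma-separated, decimal **point** (not comma),
  header row required. Both the long canonical layout and the wide
  one-column-per-concentration layout are accepted; long is what
  `write_validation_csv()` emits.

## Limitations

The prediction band uses the plug-in normal quantile: parameter
uncertainty of the fitted curve and variance function is not propagated
(no t-type inflation, no tolerance-interval machinery), so for very small
validation studies the realised coverage of the *estimated* band falls
slightly short of nominal. Interlaboratory (reproducibility) variance
functions, decision rules/guard bands, and distributions beyond
normal/lognormal are out of scope.
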