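---
title: "Neighbourhood-adjusted disease mapping: models, sampler and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighbourhood-adjusted disease mapping: models, sampler and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nabym)
```

## The estimation problem

The package estimates the effect of an areal exposure — physician density per
10,000 inhabitants is the motivating case — on small-area disease counts,
here late-stage colorectal cancer incidence at the municipality level. The
outcome for area $i$ is a count $Y_i$ compared against an expected count
$E_i$ obtained by indirect age–sex standardization: country-level rates
$r_s$ for the four strata (females 0–74, females 75+, males 0–74, males 75+)
applied to each area's population structure, $E_i = \sum_s r_s P_{is}$. The
ratio $RR_i = Y_i/E_i$ is the standardized incidence ratio.

Two threats shape the modelling. First, area counts are spatially
correlated. Second — the harder problem — an *unmeasured spatial confounder*
$U$ (working conditions, facility quality, other place-specific drivers) may
drive both the exposure and the outcome. Models that merely account for
spatial correlation can remain biased in that situation; the
neighbourhood-adjustment (NA) model below targets the bias itself.

## The BYM baseline

The Besag–York–Mollié model is the standard disease-mapping baseline:

$$Y_i \sim \mathrm{Poisson}(E_i e^{\eta_i}), \qquad
\eta_i = \beta_0 + \beta_X X_i + \gamma^\top Z_i + \phi_i + \theta_i,$$

with $\phi$ an intrinsic-CAR (ICAR) structured effect — precision
$\tau_\phi(D - W)$ built from the 0/1 contiguity matrix $W$, smoothing each
area towards its neighbours — and $\theta_i \sim N(0, \sigma_\theta^2)$ an
unstructured effect smoothing towards the overall mean. The ICAR density is
improper; `fit_bym()` handles this with an exact sum-to-zero constraint per
connected component (re-centring each sweep) rather than a diagonal jitter,
because the constraint is testable exactly. Island municipalities (degree 0)
carry only the unstructured effect and identity smoother rows, which keeps
every matrix well defined on Norway-like graphs with islands. Whether the
CAR used elsewhere is intrinsic or proper is a configuration choice
(`car_variant`, `proper_car_precision()`), since applied reports often leave
it unstated.

## The neighbourhood-adjustment model

The NA model treats the confounder as missing data and models it jointly
with the exposure. The package fixes the concrete, testable form

$$Y_i \sim \mathrm{Poisson}(E_i e^{\beta_0 + \beta_X X_i + \gamma^\top Z_i + U_i}),
\qquad U \mid X \sim N(\delta\, S^{k} X,\; Q_U^{-1}),$$

where $S$ is the row-normalized adjacency (the neighbourhood smoother,
`order` $k$ configurable, default 1) and $Q_U = (D - \alpha_U W)/\sigma_U^2$
is a *proper* CAR precision ($\alpha_U \in [0,1)$, default 0.5). The
conditional mean $B(X) = \delta S^k X$ is exactly the confounding-bias
functional: it is the part of the outcome signal that a naive regression
would attribute to the exposure. $\delta$ carries the exposure–confounder
correlation and gets a $N(0, 10^2)$ prior; $U$ is re-imputed from its full
conditional every Gibbs sweep. The published description of the method is
high-level (joint spatial modelling, different ranges of correlation); this
linear-Gaussian coupling is the package's own concretization, chosen because
it realizes the stated mechanism while making $B(X)$ explicit and every
conditional checkable against closed forms.

**Identification.** $\beta_X X + U$ with $U$ centred on $\delta S X$ is
nearly a ridge: when $X$ is so smooth that $SX \approx X$, the split between
$\beta_X$ and $\delta$ is informed only by the prior. Identification comes
from the exposure's *local* variation $X - SX$, which the confounder — by
the scale assumption that the exposure's spatial range is at least the
confounder's — cannot track. `na_spec()` records that assumption
(`alpha_x`, `alpha_u`) and by default refuses configurations that violate
it; the synthetic generator warns when asked to generate from the violating
regime, where recovery demonstrably degrades.

## Sampler

Both fitters are Metropolis-within-Gibbs samplers with the update blocks a
disease-mapping practitioner would expect; the single-site sweeps are
compiled (Rcpp), everything draws from R's seeded RNG stream, and a fit is a
pure function of `(data, graph, spec)`:

* regression coefficients: per-coordinate adaptive random-walk Metropolis
  (target acceptance ≈ 0.44, batch adaptation every 50 iterations during
  burn-in only, frozen afterwards);
* $\theta$ and $\phi$: single-site Metropolis under the iid and ICAR full
  conditionals; $\phi$ re-centred per component after each sweep;
* $U$: single-site Metropolis–Hastings with a Gaussian proposal from a local
  quadratic expansion of the Poisson log-likelihood around the current
  value (exact, acceptance 1, under the Gaussian test hook); a joint block
  update by sparse Cholesky is available for the linear-Gaussian case;
* $\delta$: exact conjugate Gaussian draw; variances
  ($\sigma_\theta^2$, $\tau_\phi^{-1}$, $\sigma_U^2$): conjugate
  inverse-gamma draws, default prior IG(1, 0.01) — a common weakly
  informative disease-mapping choice, exposed in the spec objects because
  the applied literature rarely reports it;
* an *interweaving ridge move* in `fit_na()`: propose
  $(\beta_X + \varepsilon,\; U - \varepsilon X,\; \delta - \varepsilon)$
  jointly. The outcome likelihood is exactly invariant along this direction,
  so the acceptance ratio reduces to the identification term
  $\varepsilon (X - SX)^\top Q_U(\cdot)$ plus coefficient priors. Without
  it, the weakly identified $\beta_X$–$\delta$ ridge mixes very slowly; the
  move is a sampler-efficiency device and does not alter the model.

Chain lengths default to 10,000 kept iterations after 1,000 burn-in, the
standard run length for these models; coefficients get $N(0, 10^2)$ priors.
A Gaussian-likelihood hook (`likelihood = "gaussian"`) replaces the Poisson
term with $Y_i \sim N(\eta_i, \sigma^2)$ so that the coefficient and
confounder conditionals have closed-form conjugate posteriors; the test
suite uses it to check the sampler against exact linear-Gaussian algebra
(and validated the NA fitter against the fully marginalized
generalized-least-squares posterior during development).

## Posterior summaries

`summarize_effect()` reports the quantities such studies print: the
arithmetic posterior mean of $\beta_X$ (3 decimals for display), the
equal-tailed 95% credible interval (interpolated sample quantiles;
equal-tailed rather than HPD for reproducibility), the percent change per
unit exposure $(1 - e^{\beta})\times 100$ (1 decimal), and the
geometric-mean relative risk $e^{\bar\beta}$ (2 decimals) — the centre of
the population-average exposure–response curve, whose kernel density over
$e^{\beta}$ is produced by `exposure_response_density()` (trapezoid-
normalized to integrate to 1; degenerate draws yield an explicit point-mass
representation rather than an error). Display rounding is half-away-from-
zero, matching how one-decimal percentages are conventionally printed; note
that $1 - e^{-0.028} = 2.76\%$, so a printed "2.79%" for that coefficient
implies an unrounded source value — the package documents the exact
transform and does not chase such artifacts.

## The synthetic generator

Registry data at this geography are access-restricted, so the package ships
a generator (`generate_study()`) whose defaults emulate the study anatomy
end to end: 356 municipalities on a Gabriel graph over random points
(planar, connected, mean degree ≈ 4 — a stand-in for contiguity; a lattice
and user-supplied edge lists are alternatives); populations
log-normal(log 5200, 1) split into the four strata by fixed shares
(0.38/0.12/0.38/0.12); pooled-period stratum rates (0.002, 0.02, 0.002,
0.022 cases per person) giving a few dozen expected cases in a median
municipality and a ≈ 78.5% late-stage share when a stage split is
simulated.

The exposure field is deliberately *two-scale*: a smooth regional gradient
(proper-CAR $\alpha_X = 0.95$ plus two smoothing passes) mixed with an
equal-variance iid local component (`local_mix = 0.5`), rescaled to median
≈ 1.4 per 10,000 (sd 0.5) and truncated at zero — truncation rather than a
log transform keeps the "one physician per 10,000" effect interpretation
linear. Both scales matter: the regional gradient is what a flexible
spatial random effect competes with, and the local variation is what
identifies the NA model. The confounder is $U = \delta S X + $ proper-CAR
noise at shorter range ($\alpha_U = 0.7$, marginal sd 0.15), with coupling
$\delta = 0.15$ — strong spatial confounding, chosen so the induced bias is
detectable at the replicate sizes the recovery experiments use (with
undetectable confounding the experiments would measure only noise). True
effects default to $\beta_0 = 0$, $\beta_X = -0.03$ (a test point near the
scale of published estimates, not a claim about any real data-generating
truth), and two iid standard-normal covariates with effects ±0.05.

What the generator does *not* emulate: the real municipal geography and
population registry, covariate sourcing, within-period dynamics (the study
period is pooled, as the motivating analysis pools 2012–2020), and —
importantly — the fine spatial configuration of the real confounding.
Consequently, passing recovery tests show that the estimator chain works
under the stated assumptions, not that the real-data estimates are correct.
Two specific echoes of the motivating results are only partly reproducible
under these synthetic conditions: per-replicate de-biasing comparisons are
noisy because the naive estimator's own sampling error is comparable to the
induced bias at 150 areas, and the "narrower NA interval" phenomenon
depends on the real data's confounder carrying a large exposure-scale
variance share, which the short-range synthetic confounder does not; the
acceptance suite reports both honestly rather than tuning the generator
until they appear.

## Numerical choices and degenerate inputs

* Quartile grouping uses interpolated sample quantiles with ties assigned
  to the lower group; all-identical exposures collapse to a single group
  with a warning rather than an error.
* ICAR row sums are integer-exact before $\tau$ scaling; GMRF draws for the
  intrinsic variant are taken in the positive eigenspace and re-centred per
  component (max residual component sum below $10^{-10}$ is asserted in
  tests).
* Proper-CAR draws use sparse Cholesky with permutation, so generation
  scales to the thousands of areas used in the large-sample oracle test.
* Expected counts must be strictly positive for every modelled area; zero
  or negative values raise errors naming the offending areas. Non-integer
  or negative counts are rejected by the Poisson likelihood.
* Divergent chains (non-finite log-likelihood) raise an error carrying the
  iteration index; non-finite confounder acceptance ratios raise one with
  the site index.

## Problem sizes

The test suite runs its calibration and recovery checks at 20–400 areas
with chains of 300–40,000 iterations, and the full-scale experiments (null
recovery at 100 areas and the ten-replicate confounding experiment at 150
areas with 5,000 kept draws; a 5,000-area large-sample oracle check) were
sized so the whole suite completes in a few minutes on one core — the
package's choice of simulation scale for routine verification. The analysis
scripts under `analysis/` run the complete 356-area workflow at the default
10,000-iteration chains.
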