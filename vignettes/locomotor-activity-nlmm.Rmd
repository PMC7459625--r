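---
title: "Modelling locomotor activity after irradiation: methods and design"
author: "LocoNLMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling locomotor activity after irradiation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LocoNLMM)
```

## The scientific problem

A single sub-lethal whole-body gamma-ray exposure transiently suppresses
spontaneous locomotor activity in rodents. The interesting quantities are
not per-day group differences but the *parameters of the trajectory*: how
deep the initial drop is as a function of dose, and how fast activity
returns to its pre-irradiation level. Activity panels have two dominant
nuisance structures — stable differences between animals, and day-to-day
fluctuations (room conditions) shared by all animals housed together — so
a model with *crossed* random effects is the natural frame.

## Data construction

Infrared sensors count movements per minute continuously. Because rats
are nocturnal, the package defines a day's activity as the cumulative
count over the nocturnal window, by default the half-open interval
[18:00, 06:00) spanning midnight; a night is labelled by the calendar
date on which it starts. Totals are log10-transformed. Base 10 is a
deliberate choice: baseline values around 4.3 correspond to roughly
2×10^4 movements per night, the plausible scale for per-minute infrared
counts, whereas a natural-log reading (e^4.3 ≈ 75 movements/night) would
not be. Nights with incomplete sensor coverage are flagged and excluded
rather than rescaled — no defensible rescaling rule exists without
knowing why intervals are missing — and zero-count nights are refused by
the log transform so the caller must handle them explicitly.

## The model

For animal $i$ with dose $D_i$ (Gy) on day $t$ (irradiation day $t=0$):

$$y_{it} = f(t \mid D_i, \theta) + \delta_i + \eta_t + \varepsilon_{it},$$
$$f(t \mid D, \theta) = \xi_0 + \xi_1 t + \xi_2 t^2 -
  (\beta_1 D + \beta_2 D^2)\, e^{-\omega_1 e^{-\omega_2 (D - D_0)} t}\, h(t),$$

with $\delta_i \sim N(0, \psi^2)$, $\eta_t \sim N(0, \varphi^2)$,
$\varepsilon_{it} \sim N(0, \sigma^2)$, all independent, and $h$ the
Heaviside step. Parameters and units:

| parameter | meaning | units | default handling |
|---|---|---|---|
| $\xi_0,\xi_1,\xi_2$ | baseline day polynomial | log10 activity (per day, day²) | $\xi_0$ always free |
| $\beta_1,\beta_2$ | initial decrease at $t=0$ | per Gy, per Gy² | $\beta_1$ always free |
| $\omega_1$ | recovery rate at $D_0$ | per day | always free, $\ge 0$ |
| $\omega_2$ | dose modulation of rate | per Gy | optional |
| $D_0$ | centering dose | Gy | fixed 2.75, configuration |
| $\psi^2,\varphi^2,\sigma^2$ | variance components | (log10 activity)² | mixed model only |

The crossed random effects imply, for the stacked observations, the
covariance
$\Omega = \psi^2 \mathbf{1}\{i=j\} + \varphi^2 \mathbf{1}\{t=t'\} +
\sigma^2 \mathbf{1}\{i=j, t=t'\}$, built over exactly the observed cells
so unbalanced panels work throughout. $\Omega$ is symmetric positive
definite whenever $\sigma^2 > 0$ and $\psi^2, \varphi^2 \ge 0$.

## Likelihood evaluation

The log-likelihood is the exact multivariate normal log density with the
standard $(2\pi)^{n/2}$ normalization, $n$ the number of panel cells.
Two equivalent paths are implemented:

* **dense**: Cholesky of the cell-wise $\Omega$ — always available,
  used for unbalanced panels;
* **balanced**: for a complete $A \times T$ grid, $\Omega$ has four
  eigenvalue strata — the grand mean
  ($\sigma^2 + \psi^2 T + \varphi^2 A$), animal-mean deviations
  ($\sigma^2 + \psi^2 T$, multiplicity $A-1$), day-mean deviations
  ($\sigma^2 + \varphi^2 A$, multiplicity $T-1$) and the interaction
  ($\sigma^2$) — over which both $\log|\Omega|$ and the quadratic form
  decompose, giving an $O(n)$ evaluation.

The two paths agree to ~10^-12 on every tested panel and both match a
brute-force `solve()`/`determinant()` density in the test suite.
Minimizing $Q = -2 \log L$ is identical to maximizing the likelihood.

## Fitting

$f$ is linear in $(\xi_0, \xi_1, \xi_2, \beta_1, \beta_2)$ once
$(\omega_1, \omega_2)$ are fixed, so those coefficients are concentrated
out exactly by GLS at every objective evaluation. The outer optimization
(L-BFGS-B, the classical quasi-Newton choice for smooth bounded
problems) then runs over at most five coordinates: $\log \omega_1$,
$\omega_2$, and the log variance components. Log scales enforce
positivity without constraints; estimates are reported on the natural
scale. Numerical choices, fixed once:

* convergence: `factr = 1e4` (~1e-8 relative on $Q$), `maxit = 2000`;
* box bounds $\log\omega_1 \in [-10, 10]$, $\omega_2 \in [-10, 10]$,
  log variances $\in [-25, 5]$ — wide enough to be inactive at any
  interior optimum, and preventing runaway drift along flat directions;
* starting values from the data: $\xi_0$ = mean pre-irradiation log
  activity; $\beta_1$ from day-0 group-mean drops regressed on dose;
  $\omega_1 = 1$; variance components by a method-of-moments
  decomposition of initial residuals into animal-mean, day-mean and
  interaction strata;
* deterministic (RNG-free) jittered restarts if no start converges, and
  a final polish run from the best point when the line search
  terminates abnormally;
* during model selection, every candidate is additionally warm-started
  from its best already-fitted nested submodel, so the log-likelihood
  ordering of nested specifications holds by construction;
* ML, not REML, throughout: model comparison uses AIC on full
  likelihoods. REML is deliberately out of scope.

Standard errors come from the numerically differentiated observed
information at the optimum (fixed effects on the natural scale; variance
components on the log scale, back-transformed by the delta method and to
be read as large-sample approximations). When the generating recovery
rate is fast, the likelihood is numerically flat in $\omega_1$ — the
decrease has decayed to noise level within a day, so only the $t=0$
cells carry information — and the corresponding row of the information
matrix is indistinguishable from zero. Such near-flat directions are
detected (curvature below 1e-3) and their SEs reported missing rather
than inverted into meaningless numbers; the remaining block is inverted
conditionally.

One reporting convention is deliberately unconventional and therefore
flagged prominently: tabulated p-values are **one-sided** normal tails,
$p = 1 - \Phi(|\hat\vartheta|/\mathrm{SE})$. This is the convention that
matches the interval/p-value arithmetic this model family is reported
with; a two-sided p-value is exactly twice the tabulated one. Confidence
intervals are Wald, $\hat\vartheta \pm 1.959964\,\mathrm{SE}$ at 95%.

## Model selection

The four optional terms $(\xi_1, \xi_2, \beta_2, \omega_2)$ give 16
candidate specifications per family (mixed / ordinary regression). All
are fitted; non-converged candidates are excluded with a warning; the
smallest AIC wins, with ties broken towards fewer parameters and then
lexicographically by label — a fixed, reproducible rule. AIC and BIC are
always $-2\log L + 2k$ and $-2\log L + k\log n$ with $k$ counting free
fixed effects plus variance components (3 mixed, 1 regression); the
identities are enforced by the fit class itself.

## Random effects and diagnostics

Posterior means (BLUPs) are the exact Gaussian conditional expectations
$\hat c = G Z' \hat\Omega^{-1} (y - \hat\mu)$; per-cell residuals follow
from the identity $y - \hat\mu = \hat\delta_i + \hat\eta_t +
\hat\varepsilon_{it}$, which holds exactly by construction and is
asserted in tests. Shrinkage behaves as theory requires: predictions
vanish as the prior variance goes to zero and their dispersion grows
monotonically with it.

Serial correlation of the day effects is checked with the Durbin–Watson
ratio $\sum_t (\hat\eta_t - \hat\eta_{t-1})^2 / \sum_t \hat\eta_t^2$.
Because $\hat\eta_t$ are posterior means, not regression residuals, the
classical DW null tables do not apply; the p-value is computed by a
permutation test (default 10,000 reorderings, fixed seed, two-sided tail
in $|DW - 2|$). This is a documented approximation of our own choosing —
the reference analyses of this model family do not state how their DW
p-value was obtained, and the permutation value is not expected to
reproduce a table-based one.

## Dose–response summaries

The initial decrease at dose $D$ is $\hat\beta_1 D + \hat\beta_2 D^2$
with a delta-method interval using gradient $(D, D^2)$ against the
fixed-effect covariance block — checked in tests against a parametric
bootstrap. At $D = 0$ the decrease is identically zero with a zero-width
interval. The recovery rate is $r(D) = \hat\omega_1
e^{-\hat\omega_2 (D - D_0)}$, common to all doses when $\omega_2$ is
dropped. "Recovery time" needs a convention because the model recovers
only asymptotically: the package defines it as the time for the
decrease to fall to a fraction (default 5%) of its initial magnitude,
$t^* = -\log(\text{fraction})/r(D)$, with the fraction exposed as a
parameter. No interval is attached to $t^*$.

## The synthetic-data generator

Real panels of this kind are rarely deposited, so the generator is a
first-class module: it draws $\delta, \eta, \varepsilon$ from their
generating normals and assembles $y$ by the exact cell identity, with
per-component RNG streams derived from one root seed (so replicate $r$'s
panel never changes when more replicates are requested). Defaults
reproduce the study conditions this model family was developed for:
4 animals per group at 0/2.0/3.5/5.0 Gy, days −3..20, $\xi_0 = 4.319$,
$\beta_1 = 0.066$, $\beta_2 = -0.006$, $\omega_1 = 9.063$,
$(\psi^2, \varphi^2, \sigma^2) = (0.0018, 0.0019, 0.0015)$,
$D_0 = 2.75$ Gy.

Raw circadian counts are emulated by an inhomogeneous Poisson process
with two rates: within each night the rate is set so the expected
nightly total equals $10^{y_{it}}$, and the daytime rate is a fixed
fraction (default 0.25) of it — the simplest process with the observed
steeper-at-night cumulative-count shape. It makes no claim to match real
sensor statistics (no ultradian rhythm, dead time, or weight effects).
Consequently, passing tests demonstrate correctness of the estimation
machinery *under the model*, not robustness to real-data features such
as missing sensor intervals, non-Gaussian fluctuations, or activity
trends the polynomial cannot capture.

Simulation studies in the tests use 200 recovery replicates at the
study-sized 16 × 24 design (the scale at which Monte-Carlo error on the
mean estimates is a few parts in 10^3) and 50 replicates for the
selection-consistency check; the balanced-path likelihood makes each of
the several thousand fits involved take a few hundredths of a second.

## Known limitations

* With a fast generating recovery rate, $\omega_1$ is weakly identified
  (flat likelihood above ~5/day at these designs); its point estimate
  then carries little information and its SE is reported missing.
  Estimates of the *decrease* parameters are unaffected.
* Variance-component SEs are log-scale Wald approximations; profile or
  bootstrap intervals are out of scope.
* ML variance estimates carry the usual small downward finite-sample
  bias relative to REML (about 1% on $\sigma^2$ at this design, visible
  in the recovery experiment).
* The covariance family is fixed (exchangeable crossed effects); AR(1)
  day effects or group-heteroscedastic variants are not implemented.
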