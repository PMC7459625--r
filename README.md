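# LocoNLMM

Non-linear mixed effects modelling of rodent locomotor activity around a
single whole-body gamma-ray exposure.

Whole-body irradiation transiently suppresses spontaneous activity in
rodents — an objective behavioural correlate of the prodromal radiation
syndrome. Experiments that track activity over weeks produce longitudinal
panels with strong inter-animal differences and shared day-to-day
fluctuations, which per-timepoint testing cannot disentangle from the
dose effect. LocoNLMM is for biostatisticians and radiobiologists who
want to model such panels directly: how large the initial drop in
activity is as a function of dose, and how fast it recovers.

## The model

Nightly movement counts (infrared sensor, 18:00–06:00 window) are summed
per night and log10-transformed into "daily activity" y_it for animal i
(dose D_i Gy) on day t (day 0 = irradiation). The model is

    y_it = f(t | D_i, θ) + δ_i + η_t + ε_it

    f(t | D, θ) = ξ0 + ξ1 t + ξ2 t²
                  − (β1 D + β2 D²) · exp[−ω1 e^{−ω2 (D − D0)} · t] · h(t)

with crossed random effects δ_i ~ N(0, ψ²) (individual differences),
η_t ~ N(0, φ²) (daily fluctuation shared by all animals) and
ε_it ~ N(0, σ²) (measurement error); h(t) is the Heaviside step and
D0 = 2.75 Gy a fixed centering dose. The baseline polynomial describes
drift without irradiation, β1 D + β2 D² is the initial decrease at t = 0,
and ω1 e^{−ω2 (D − D0)} is the dose-specific exponential recovery rate
(per day). Setting ψ² = φ² = 0 gives the ordinary non-linear regression
model (NLRM).

Estimation is direct maximum likelihood on the exact multivariate-normal
likelihood with covariance Ω = ψ² (same animal) + φ² (same day) +
σ² (same cell), via L-BFGS-B with the linear coefficients concentrated
out by GLS. Submodels (toggling ξ1, ξ2, β2, ω2) are compared by AIC;
random effects are predicted by posterior means (BLUPs); dose–response
summaries carry delta-method confidence intervals.

## Worked example

Simulate a study-sized panel (16 rats, 4 dose groups at 0/2/3.5/5 Gy,
days −3..20) from the model, fit the optimal mixed specification, and
summarise the dose–response:

```r
library(LocoNLMM)
design <- simulationDesign(seed = 2020)   # study defaults, known truth
truth  <- simulatePanel(design)
fit    <- fitActivityModel(truth@panel, optimalModel())
fit
#> Non-linear mixed effects fit (NLMM)
#>        estimate     se
#> xi0      4.3346 0.0155
#> beta1    0.0700 0.0172
#> beta2   -0.0069 0.0034
#> omega1   5.8442     NA
#>   variance components: psi2 = 0.002708, phi2 = 0.001578, sigma2 = 0.001478
#>   logLik 642.503 | AIC -1271.01 | BIC -1243.35 | n = 384, k = 7
```

`beta1`/`beta2` say the immediate post-irradiation drop in log10
activity grows with dose but sub-linearly (negative quadratic term);
`omega1` is the common recovery rate per day — here so fast that its
likelihood direction is flat and the SE is honestly reported missing
(the drop has essentially vanished by the next night). The variance
components split the residual variation into individual differences,
shared daily fluctuation and measurement error.

```r
doseResponseTable(fit)
#>   dose decrease     se ci_lower ci_upper recovery_rate recovery_time
#> 1  0.0    0.000 0.0000   0.0000    0.000          5.84            NA
#> 2  2.0    0.112 0.0218   0.0698    0.155          5.84         0.513
#> 3  3.5    0.161 0.0238   0.1141    0.207          5.84         0.513
#> 4  5.0    0.178 0.0253   0.1282    0.227          5.84         0.513
```

A decrease of 0.178 at 5 Gy means activity on the irradiation night is
10^0.178 ≈ 1.5-fold lower than baseline. Diagnostics:

```r
pred <- predictRandomEffects(fit, truth@panel)   # BLUPs per animal / day
durbinWatson(pred@etaHat, seed = 1)              # serial-correlation check
#> DW = 2.47 (permutation p = 0.237)
varianceShares(fit)$share                        # % of total variance
#>  psi2  phi2 sigma2
#>  47.0  27.4   25.6
```

Raw sensor counts can be ingested with `readMovementCounts()` →
`nightlyActivity()` → `assemblePanel()`; a YAML-configured pipeline
(`cmdSimulate`, `cmdFit`, `cmdSelect`, `cmdDiagnose`, with a thin
wrapper in `inst/scripts/loco-pipeline.R`) ties the stages together.

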