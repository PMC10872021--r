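---
title: "Models and methods behind thermoclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermoclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

thermoclone analyses microgeographic thermal adaptation in clonal
zooplankton metapopulations: rock pools metres apart can differ in thermal
regime as much as sites hundreds of kilometres apart in latitude, and a
clonal organism such as *Daphnia magna* lets genetic and non-genetic
components of trait variation be separated directly, because replicate
individuals of a clone are genetically identical. This vignette explains the
models the package implements, the choices behind their defaults, and what
the synthetic-data machinery does and does not establish.

## 1. Pool thermal metrics

Each pool contributes a daily series of maximum and mean water temperature
over a growing-season window (day-of-year 166–288 by default). Five metrics
summarise a pool's thermal regime:

* **mean daily mean temperature** over the window (used as
  `|mean - 20 °C|`, the mismatch between pool and rearing temperature);
* **hottest-month mean daily maximum** (August by default, configurable, or
  `"empirical"` to pick the warmest observed month) — the within-generation
  thermal extreme;
* **daily SD** of detrended daily maxima — within-generation variability;
* **predictability** — the range (days) of a Gaussian temporal-correlation
  model of the detrended maxima: the lag over which temperatures remain
  autocorrelated, hence how far ahead today's temperature is informative;
* **seasonal range** (max − min of observed daily maxima) —
  among-generation variability. It is computed on the observed maxima, not
  the fitted trend, so one hot day moves it; this matches the "range"
  reading of the definition and is the conservative choice.

`fit_gls_quadratic()` removes the seasonal component with a quadratic
generalized least-squares fit in day-of-year (via `nlme::gls`), modelling
residual correlation between days $h$ apart as
$\rho(h) = (1-\nu)\exp\{-(h/\phi)^2\}$. Estimation is joint maximum
likelihood over trend and correlation parameters, multi-started over initial
ranges $\{1, 3, 5, 7, 14\}$ days (the Gaussian-correlation likelihood can be
multimodal) with the best converged fit kept. The day covariate is centred
and scaled internally for conditioning; coefficients are reported on the
day-of-year scale.

**Why a nugget by default.** The nugget-free Gaussian correlation matrix is
numerically near-singular at ranges of a few days with daily sampling (the
Gaussian kernel is infinitely smooth, so its eigenvalues decay
super-exponentially). In simulate-and-refit experiments (true range 5 days,
SD 1.5 °C, 122 days, 50 seeds) the nugget-free maximum-likelihood range
collapses to about 3 days, while the nugget fit recovers a mean range of
about 4.9 days and mean residual SD about 1.40 °C. The nugget ($\nu$)
absorbs measurement-scale noise and makes the range identifiable; nugget-free
fitting remains available via `nugget = FALSE`. The residual SD is the
sample SD of the detrended residuals — the series' day-to-day variability
after removing the seasonal curve. The quadratic absorbs some low-frequency
residual variance, so this estimator is mildly conservative (a few percent
at strong autocorrelation).

Series where the quadratic explains everything (noiseless or constant input)
short-circuit to an exact ordinary-least-squares answer with residual SD 0
and an undefined (NA) range. Pools whose fit does not converge are flagged
and dropped from the climate table with a warning, and runs with more than
20% of days missing are flagged.

One terminological wrinkle: the daily-variability metric is sometimes called
a "monthly" SD in field summaries; here it is implemented as the SD of
detrended daily residuals across the whole window, which is the estimator
the detrending procedure actually produces.

## 2. Fitness from brood schedules

Each female's fitness is the intrinsic rate of natural increase $r$ (per
day) solving the Lotka–Euler equation over her first and second broods:

$$\sum_k l_{x_k}\, m_{x_k}\, e^{-r x_k} = 1$$

with survivorship $l_x = 1$ at each observed brood (she was demonstrably
alive when she reproduced) and every offspring counted, since reproduction
is clonal and all-female. Only the first two broods enter even if more were
recorded. Individuals enter the analysis only if they matured (≥ 1 non-empty
brood) and were monitored ≥ 15 days (boundary inclusive), giving every
female comparable opportunity to produce two broods.

$f(r) = \sum_k m_k e^{-r x_k} - 1$ is strictly decreasing, so the root is
unique; it is bracketed, solved with `uniroot`, and polished by bisection to
$|f(r)| < 10^{-12}$. With ages in days, $r$ is **per day** — worth stating
prominently since growth rates are sometimes reported per week or per
generation. A single brood of $m$ offspring at age $x$ gives the closed form
$r = \ln(m)/x$, used as an exactness oracle in the tests.

## 3. The twelve hierarchical models

All models are Gaussian linear mixed models of one response (thermal
tolerance CTmax, °C, or fitness $r$, per day):

$$y_i = \mathbf{x}_i^\top\boldsymbol\beta + c_{\mathrm{clone}(i)} +
p_{\mathrm{pool}(i)} + t_{\mathrm{trial}(i)} + \varepsilon_i$$

with a year fixed effect throughout (two years is too few to estimate a
year variance), a trial random effect only for CTmax (assay batches share a
water bath), and priors $\beta_j \sim N(0, 1000)$ and every standard
deviation $\sim U(0, 100)$. The registry (`model_registry()`) freezes the
twelve structures; see its help page for the full list. The key axes are:

* **M1 family** (20 °C individuals only): nested sequence from no clone
  term (no genetic variation) to clone, clone + pool, clone + pool + a pool
  thermal covariate (microgeographic adaptation), plus M1-4 in which the
  clone SD differs among pools (fluctuating selection).
* **M2 family** (both temperatures): developmental-plasticity fixed effect
  and its interactions with daily temperature variation (M2-2) or
  predictability (M2-3).
* **M3 family** (both temperatures, built from M1-1 with no pool term):
  temperature-specific intercept and year effect, with the clone variance,
  the error variance, or both allowed to differ between developmental
  temperatures. When the clone variance is temperature-specific, clone
  deviations are drawn independently per temperature — there is no
  cross-temperature genetic correlation parameter, because the variance
  structure being tested is purely heteroscedastic.

Pool covariates are constant within pool; they are centred and scaled
internally for mixing and coefficients are mapped back to the raw covariate
scale for reporting. The uniform prior is applied to standard deviations
(the common hierarchical-modelling idiom for a "uniform variance-parameter
prior"); `priors` is an argument, so a variance-scale prior bound can be
emulated by adjusting `sd_upper`.

### The Gibbs sampler

`sample_posterior()` is a blocked Gibbs sampler written for exactly this
model family:

* $\boldsymbol\beta$: multivariate-normal conjugate update weighted by the
  per-observation error precision;
* each random-effect level: scalar normal conjugate update;
* each SD: under the uniform prior the full conditional of the variance
  given $k$ effect values with sum of squares $SS$ is inverse-gamma with
  shape $(k-1)/2$ and rate $SS/2$, truncated to SD < 100; it is drawn by
  rejection from the untruncated inverse-gamma, with a stepping-out slice
  sampler on $\log\sigma$ as the fallback when the shape is non-positive
  (a one-level variance group, which the frame builder also warns about).

Chains start overdispersed from chain-specific seeds; identical seed and
settings reproduce draws bit-for-bit, and observations are canonically
sorted internally so the posterior is invariant to input row order. The
default iteration counts mirror the published settings (10k/5k/5 for
M1-0–M1-3, 30k/25k/5 for M1-4, 75k/25k/50 for M2/M3); the sampler is
validated against a closed-form conjugate posterior, a simulation-based
calibration harness, and an independent JAGS fit of the same model in the
test suite. Small variances mix slowest (the usual funnel geometry of
centred parameterizations); the convergence diagnostic to watch is the
split-chain $\hat R$ of the group-specific clone SDs.

## 4. Model comparison and diagnostics

`psis_loo()` re-implements Pareto smoothed importance sampling
leave-one-out cross-validation from the published algorithm: per
observation, raw importance ratios $\propto e^{-\ell_{si}}$; the largest
$M = \min(0.2S,\ 3\sqrt S)$ ratios are replaced by expected order statistics
of a generalized Pareto distribution fitted to the tail exceedances with the
Zhang–Stephens profile-posterior estimator (tail-shape $k$ regularized
towards 0.5 by a weight-10 prior); weights are truncated at the raw maximum;
and each pointwise ELPD is a log-sum-exp–stabilised weighted average.
$p_\mathrm{eff} = \sum_i(\mathrm{lpd}_i - \mathrm{elpd}_i)$ and
$\mathrm{SE} = \sqrt{n\,\mathrm{Var}(\mathrm{elpd}_i)}$. Observations with
$k > 0.7$ are recorded as unreliable in the result (a warning, not a
failure). The log-likelihood fed in is **conditional** on the sampled random
effects — the convention for exporting pointwise likelihoods from
hierarchical models — so the LOO question asked is "predict this individual
given its clone", not "predict a new clone".

`compare_models()` sorts by ELPD and reports each model's deficit
$\Delta$ELPD with the SE of the *pointwise difference*. A model is
**supported** when $|\Delta| \le 2\,\mathrm{SE}(\Delta)$ — i.e. it is
statistically indistinguishable from the best model. (Stated the other way
around — support when the deficit *exceeds* twice its SE — the rule would
grant support to clearly worse models; the implemented direction is the one
consistent with how such comparisons are actually called.) Ties are broken
by input order, and exactly one row has $\Delta = 0$.

`gelman_rubin()` computes the split-chain potential scale reduction factor
(each chain halved, classic PSRF across half-chains); < 1.1 was the
historical convergence bar, < 1.01 the stricter modern one. Parameters with
zero within-chain variance are flagged degenerate rather than silently
passed. `ppc_pvalues()` simulates replicate data per retained draw —
re-drawing residual error conditional on the sampled random effects by
default (a goodness-of-fit test of the observation model), or re-drawing
the random effects too with `redraw_random = TRUE` — and reports Bayesian
$p$-values for the mean and variance; values near 0.5 indicate adequate
fit. The conditional default makes the check conservative (p-values
concentrate near 0.5 for a true model), which is the behaviour the
calibration test asserts.

## 5. Heritability and temperature contrasts

With clones, the among-clone variance is the total genetic variance, so
heritability is **broad-sense**:

$$H^2 = \frac{\sigma^2_\mathrm{clone}}{\sigma^2_\mathrm{clone} +
\sigma^2_\varepsilon}$$

computed draw-wise, summarised by posterior medians and central 95%
credible intervals. The trial variance is deliberately excluded from the
denominator even for CTmax: $H^2$ then refers to the assay-adjusted
phenotype, and including a batch nuisance variance would deflate it.
`temperature_contrast()` reports per-draw differences between developmental
temperatures (median and 95% CI) together with the percent change **of the
posterior medians** — a point statement paired with a difference CI, which
is how such contrasts are conventionally phrased. A per-draw percent-change
CI is available behind `percent_change_draws = TRUE`; percent change of a
ratio of medians and the median of per-draw percent changes can differ
noticeably when the denominator is small, which is why the default is the
explicit, reproducible medians-based definition.

## 6. The synthetic-data generator

`synthetic_config()` encodes the study conditions the package is designed
around: 10 pools (4 sampled in both years, 2 in the first only, 4 in the
second only), 13 clones per pool, 2–3 individuals per clone per
developmental temperature, CTmax trials in batches of ~15 individuals.
Default phenotype parameters sit on the scales such assays produce — CTmax
intercept 37.5 °C, later-year effect +0.9 °C, plasticity +0.4 °C, clone SDs
0.4/0.2 °C at 20/25 °C, residual SD 0.45 °C; fitness intercept 0.189 per
day, year +0.056, plasticity +0.029, with clone SDs 0.02/0.03 and residual
SDs 0.03/0.04 per day chosen to give heritabilities of the same order as
the thermal trait. Pool covariate slopes default to zero, so covariate
effects are opt-in for power studies.

Temperature series are a quadratic seasonal trend peaking in early August
plus multivariate-normal deviations with the same Gaussian correlation the
fitting model assumes (Cholesky of the correlation matrix, jittered by at
most $10^{-4}$ on the diagonal if numerically non-positive-definite, and
logged when that happens). Life histories are built by **inverting the
Euler map**: brood ages are drawn (first brood 8–12 days, gap 3–5 days),
then integer brood sizes are chosen so the realized $r$ from
`solve_euler()` matches the individual's latent fitness up to rounding;
the per-individual rounding error is recorded, and unattainable targets are
retried with fresh ages a bounded number of times before erroring. Latent
fitness below zero is clamped to zero before inversion (a female cannot
produce a negative brood), so the realized fitness floor is 0 — matching
how empty-brood individuals behave in real schedules.

What the generator does **not** emulate: seasonal succession in clone
composition, maternal effects (handled experimentally by two lab
generations), non-Gaussian tails in CTmax, among-pool covariance of
climate metrics beyond what the per-pool knob grids imply, and mortality
before assay. Passing recovery tests on this generator therefore shows the
estimators are correct under the declared model, not that the model is true
of any particular field system.

## 7. Power and design-sensitivity harness

`run_power_sim()` is a coefficient-CI power analysis: for each true-effect
grid point it generates replicate studies, fits the scenario's model
(M1-3's pool-temperature slope; M2-2's or M2-3's interaction), and reports
the fraction of replicates whose 95% credible interval excludes zero, plus
bias and RMSE of the posterior-median estimate. The `inds_per_clone`
scenario varies individuals per clone at a fixed slope instead — a design
sensitivity check. This harness is a deliberate re-specification: it
answers power and design questions in kind (CI-exclusion rates, bias,
RMSE) with the package's own effect-size grids rather than reproducing any
particular published simulation; the default "biologically meaningful"
CTmax slope grid includes 0.1 °C per °C of pool temperature, configurable. The harness
default config is scaled down (6 clones per pool, 2 individuals per clone
per temperature, reduced MCMC of 1,200 iterations) so 200-replicate runs
finish in minutes; all replicate seeds derive deterministically from the
master seed.

## 8. Problem sizes and numerical choices

Defaults used by the test suite and acceptance script, chosen as the
package's own reduced-but-faithful working sizes: recovery checks fit M3-3
to ~650 observations (130 clones × 2–3 × 2 temperatures) with 2 chains of
8,000 iterations (burn-in 1,500, thinning 5); conjugate and LOO oracles use
n = 20–50 with 2,000–5,000 retained draws; the variogram oracle uses 122-day
series over 50 seeds; power runs use 200 replicates at the reduced scale.
Tolerances asserted in tests come from the oracle structure (closed forms to
1e-10; Monte-Carlo quantities to 3 Monte-Carlo SEs; calibration rates to
binomial bands at the stated replicate counts).

Degenerate inputs are handled explicitly rather than by crashing: constant
responses drive the error SD to zero (and the PSIS tail fit detects the
flat-weight case), one-level variance groups warn, noiseless temperature
series short-circuit, and empty phenotype tables produce empty outputs with
zeroed exclusion counts.

## 9. Known limitations

* LOO is conditional on sampled random effects; marginal (new-clone) LOO is
  out of scope and would require integrating the likelihood over levels.
* The M3 family has no cross-temperature genetic correlation; a bivariate
  clone model would be the natural extension.
* The sampler is centred-parameterization Gibbs: adequate here (validated
  mixing at the study's scales), but small-variance groups mix slowly and
  would benefit from parameter expansion if pushed to much smaller designs.
* Narrow-sense heritability, evolvability metrics, survivorship estimation
  and spatial covariance among pools are deliberately not implemented.
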