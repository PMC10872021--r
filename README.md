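# thermoclone

Thermal adaptation and heritability analysis for clonal rock-pool
metapopulations.

Freshwater rock pools metres apart can differ in maximum water temperature
as much as sites separated by a thousand metres of elevation. For clonal
zooplankton such as *Daphnia magna* — where replicate individuals of a
clone are genetically identical — this microgeographic mosaic is a natural
laboratory for asking whether thermal tolerance and fitness are locally
adapted, whether thermally variable pools harbour more genetic variation or
plasticity, and what warming does to evolutionary potential. thermoclone
implements the full quantitative pipeline for such studies:

* **Pool thermal metrics** — quadratic generalized-least-squares detrending
  of daily maximum temperature with a Gaussian temporal-correlation model,
  yielding daily SD, predictability (variogram range, days), hottest-month
  mean daily maximum, mean daily mean, and seasonal range per pool.
* **Fitness** — the intrinsic rate of natural increase *r* (per day) for
  each female, solving the Lotka–Euler equation
  `Σ_k m_k exp(−r x_k) = 1` over her first and second broods, with the
  standard inclusion filters (matured; monitored ≥ 15 days).
* **Twelve Bayesian hierarchical variance models** (a frozen registry:
  M1-0…M1-4, M2-0…M2-3, M3-0…M3-3) for either response, fitted by a
  built-in Gibbs sampler under N(0, 1000) coefficient priors and
  Uniform(0, 100) SD priors, covering microgeographic adaptation,
  fluctuating selection, developmental plasticity, and
  temperature-dependent variance components.
* **Model comparison** by PSIS-LOO (Pareto smoothed importance sampling
  leave-one-out cross-validation, re-implemented from the published
  algorithm) with the two-SE support rule, split-chain Gelman–Rubin
  diagnostics, and posterior predictive checks of means and variances.
* **Broad-sense heritability** `H² = σ²_clone / (σ²_clone + σ²_ε)` per
  developmental temperature, with posterior-median percent change and
  credible intervals of the per-draw differences between temperatures.
* **A fully seeded synthetic-study generator** (temperature series, clonal
  phenotypes, and brood schedules built by inverting the Euler map) plus a
  power / design-sensitivity simulation harness, so the whole pipeline is
  testable without any field data.

See `vignettes/thermoclone-methods.Rmd` for the models, priors, numerical
choices and limitations.

## Worked example

Generate a synthetic study at the default design (10 pools, 13 clones per
pool, 2–3 individuals per clone at each of 20/25 °C), compute fitness, fit
the temperature-dependent variance model, and summarise heritability:

```r
library(thermoclone)

cfg   <- synthetic_config()
study <- generate_phenotypes(cfg, seed = 1)

## fitness from the generated brood schedules
ind <- study$individuals
ft  <- fitness_table(data.frame(
  individual_id = ind$individual_id, clone_id = ind$clone,
  pool_id = ind$pool, year = ind$year, dev_temp = ind$dev_temp,
  age_first_brood_d = ind$age_first_brood_d,
  size_first_brood = ind$size_first_brood,
  age_second_brood_d = ind$age_second_brood_d,
  size_second_brood = ind$size_second_brood,
  days_monitored = ind$days_monitored))
tapply(ft$r, ft$dev_temp, mean)

## temperature effects on CTmax variance components (model M3-3)
fit <- sample_posterior(
  model_registry("M3-3", "ctmax"), study$observations$ctmax,
  settings = list(n_iterations = 6000L, n_burn_in = 1000L, thin = 5L,
                  n_chains = 2L),
  seed = 1)
max(gelman_rubin(fit))          # convergence check, want < 1.1
temperature_contrast(fit)
```

Output from this exact script:

```
       20        25
0.2292318 0.2567530

[1] 1.016626

Temperature contrast (20 vs 25 degC)
  V_G 20: 0.16  25: 0.01292  diff(20-25): 0.145 [0.08367, 0.2218]  change: -91.9%
  V_E 20: 0.1924  25: 0.2691  diff(20-25): -0.07641 [-0.138, -0.01518]  change: +39.9%
  H2  20: 0.4553  25: 0.0454  diff(20-25): 0.4002 [0.2458, 0.5317]  change: -90.0%
```

Reading it: mean fitness is ~0.23 per day at 20 °C and ~0.26 per day at
25 °C (the generator's built-in plasticity effect). All chains mixed
(max split-chain R-hat 1.02 < 1.1). From model M3-3, the genetic variance
of CTmax is much lower at the warmer developmental temperature (95% CI of
the 20 − 25 °C difference excludes zero), so broad-sense heritability falls
from ~0.46 to ~0.05. The generating truth is H² = 0.44 at 20 °C and 0.16
at 25 °C: the 20 °C estimate is on target, while this particular
realization underestimates the (small) 25 °C genetic variance — exactly
the kind of single-study scatter the package's recovery harness
quantifies across 100 replicates.

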