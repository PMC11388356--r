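# siderotrait

Quantitative analysis of how copper stress reshapes siderophore production
in a compost bacterial community co-evolving with a focal strain
(*Pseudomonas fluorescens* SBW25).

Siderophores are secreted metal-chelating compounds: they scavenge iron,
and they detoxify metals such as copper by binding them outside the cell.
Because they act in a shared environment they are community-wide public
goods, and copper-imposed selection can move their distribution both by
**ecological species sorting** (changes in which taxa are abundant) and by
**evolution within a species**. This package implements the full
quantitative toolchain needed to measure those changes from colorimetric
assay plates to posterior contrasts:

* **CAS quantification** — chrome azurol S reads to per-isolate scores,
  `s = [1 − A630/A630_ref] / OD600`, with dataset-wide min-zero
  standardization for negative reference-corrected reads.
* **Fitness statistics** — Malthusian growth rates
  `m = ln(N1/N0)/t` (per hour), relative fitness `r = m_a/m_b`, selection
  rates `s = m_a − m_b`, Cohen's *d* effect sizes, Spearman rank
  correlations with midrank ties, and the 2×2 factorial linear model for
  treatment marginal means.
* **A hierarchical Bayesian heteroscedastic model** of isolate scores:

  ```
  y_i        ~ Normal(lambda[group_i, replicate_i], sigma[group_i])
  lambda_jk  ~ Normal(nu_j, tau_j)          nu_j = alpha[X1_j] + beta[X1_j] * X2_j
  alpha_t    ~ HalfNormal(0, 1)             beta_t ~ Normal(0, 0.25)
  sigma_j, tau_j ~ Exponential(scale 0.2)
  ```

  where `X1` indexes isolate type (community vs. SBW25) and `X2` flags
  copper. Separate residual SDs per type × copper group capture the fact
  that community isolates are a mixture of unrelated strains while SBW25
  clones started isogenic. The package provides MCMC sampling with
  rank-normalized split R-hat / ESS diagnostics, MAP point estimates, 95%
  highest-posterior-density intervals, derived contrasts (combined copper
  effect `beta1 + beta2`, type differences with and without copper, copper
  effects on the residual SDs), and PSIS-LOO comparison of
  residual-variance structures (4, 2 or 1 sigma parameters).
* **A seeded synthetic-data generator** that emulates the factorial
  microcosm experiment (4 groups × 6 replicate microcosms × up to 24
  isolates, with binomial isolate dropout), so every stage is testable
  without downloads.

## Worked example

```r
library(siderotrait)

cfg      <- synthetic_config(seed = 1)      # the stated experimental world
isolates <- simulate_siderophore(cfg)       # 536 isolates (dropout ~ 8.9%)
fit      <- sample_posterior(isolates, model_spec("per_group"), seed = 1)
map      <- map_estimate(isolates, model_spec("per_group"), seed = 1,
                         fit = fit)
derived_contrasts(fit, map = map)
```

```
                           name estimate  hpd_low hpd_high
1               combined_effect -0.00133 -0.05347  0.05123
2           type_diff_no_copper  0.22768  0.18795  0.26759
3              type_diff_copper  0.12775  0.09375  0.16146
4      copper_reduction_of_diff  0.09993  0.04575  0.15023
5 sigma_copper_effect_community -0.03199 -0.04901 -0.01605
6     sigma_copper_effect_SBW25  0.00174 -0.00453  0.00804
```

Reading the output: the copper effects on the two isolate types cancel
(`combined_effect` straddles 0), while the SBW25-vs-community trait gap
shrinks from 0.228 without copper to 0.128 with copper — a significant
reduction of 0.100 [0.046, 0.150]. Copper also compresses the residual
variation among community isolates (`sigma` falls by ~0.032) while leaving
SBW25 variation unchanged. That is the trait-convergence signature: copper
selects against siderophore extremes, pulling the high-producing focal
strain down and the low-producing community up.

## Command line

```sh
inst/exec/siderotrait simulate --seed 1 --out runs/demo
inst/exec/siderotrait fit --isolates runs/demo/isolates.csv --out fit.json
inst/exec/siderotrait loo --isolates runs/demo/isolates.csv --out loo.json
inst/exec/siderotrait run --config config.json --seed 1 --out runs/full
```

`run` drives the whole pipeline from a JSON config (synthetic generator
*or* input CSVs with an optional `column_map` for foreign column names) and
writes CSV/JSON outputs plus a manifest with MD5 hashes and the seed.

## Vignette

`vignettes/siderophore-trait-convergence.Rmd` documents the model and its
assumptions, the sampler design, all numerical conventions (HPD ties, MAP
marginalization, Spearman p-values), what the synthetic generator does and
does not emulate, and known limitations.
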