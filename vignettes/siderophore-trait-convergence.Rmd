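---
title: "Modeling siderophore trait convergence under copper stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling siderophore trait convergence under copper stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siderotrait)
```

## The scientific question

Copper stress changes how much siderophore a compost bacterial community
produces, and it changes how much the focal strain *Pseudomonas
fluorescens* SBW25 produces as it evolves inside that community. The two
responses can point in opposite directions: species sorting may favor
higher-producing taxa in the community while within-species evolution
lowers production in a strain that started out as a high producer. The core
quantitative question is whether the two distributions *converge* — whether
copper selects against siderophore extremes — and by how much.

`siderotrait` answers this with (i) assay-level quantification, (ii)
isolate-level fitness and effect-size statistics, and (iii) a hierarchical
Bayesian heteroscedastic model whose derived posterior contrasts measure
convergence directly.

## The hierarchical model

Each assayed isolate `i` belongs to one of four groups `j` (community or
SBW25, with or without copper; canonical order `group_layout()`) and to a
replicate microcosm `k` within that group:

$$y_i \sim N(\lambda_{j[i],k[i]},\ \sigma_{v(j[i])}), \qquad
  \lambda_{j,k} \sim N(\nu_j, \tau_j), \qquad
  \nu_j = \alpha_{X1_j} + \beta_{X1_j} X2_j$$

with priors $\alpha_t \sim N^+(0,1)$, $\beta_t \sim N(0, 0.25)$,
$\sigma_j, \tau_j \sim \text{Exponential}(0.2)$. The replicate means
$\lambda$ absorb shared microcosm history; the group-specific residual SDs
$\sigma_j$ accommodate the strongly unequal spread of community isolates
(a mixture of unrelated strains) versus SBW25 clones (initially isogenic).
The variance map $v(\cdot)$ is configurable: four SDs (one per group), two
(by isolate type or by copper), or one, and PSIS-LOO decides which
structure the data support.

### Prior parameterization

The model statement leaves two readings open: $N(0, 0.25)$ as an SD or a
variance, and $\text{Exponential}(0.2)$ as a scale (mean) or a rate. We
parameterize Normal distributions by (mean, SD) and the Exponential by its
scale, the conventions of the probabilistic framework the model family
comes from, and the readings that put the priors on the scale of the
posteriors one actually obtains ($\sigma \approx 0.03$–$0.10$). Both
choices are exposed as `model_spec()` flags (`beta_prior_as_variance`,
`exp_prior_as_rate`) rather than hard-coded, so the alternative reading is
one argument away.

### Index conventions

`X1` maps groups to isolate types with 1 = community and 2 = SBW25, and
`X2 = 1` means copper present. Under this coding the type difference
*without* copper is $\alpha_2 - \alpha_1$ and the difference *with* copper
is $(\alpha_2 + \beta_2) - (\alpha_1 + \beta_1)$. This is the numerically
consistent convention: with SBW25 the high producer, $\alpha_2 - \alpha_1$
is the large baseline gap, and the copper-driven reduction of the gap
equals $\beta_1 - \beta_2$, the difference of the two copper effects.

## Sampling: why blocked Gibbs instead of NUTS

The model is conditionally conjugate: given the scales, $\lambda$,
$\alpha$ and $\beta$ have closed-form Gaussian (for $\alpha$,
truncated-Gaussian) full conditionals, and $\sigma$, $\tau$ are univariate
and log-concave enough for slice sampling. `sample_posterior()` therefore
runs a blocked Gibbs sampler with two refinements that matter in practice:

* **Joint $(\alpha_t, \beta_t)$ draws.** $\beta_t$ is identified only
  through $\alpha_t + \beta_t$, so sequential updates random-walk along a
  correlation ridge. Each scan draws $\alpha_t$ from its truncated marginal
  and $\beta_t$ from its exact conditional.
* **Ancillarity–sufficiency interweaving.** The centered parameterization
  mixes poorly when $\tau$ is small relative to
  $\sigma/\sqrt{n_\text{cell}}$ (the classic funnel). After the centered
  scan, $\alpha$, $\beta$ and $\tau$ are re-drawn in the non-centered
  parameterization $\lambda = \nu + \tau\eta$ with $\eta$ held fixed.

With both in place, experiment-scale fits (4 chains × 1,000 post-warmup
draws after 1,000 warmup scans, the package defaults) finish in a few
seconds with all rank-normalized split R-hat values below 1.01 and bulk
ESS above 1,000 for every parameter. A run with any R-hat at or above 1.01
is *flagged* (`converged = FALSE`, plus a warning), never silently
accepted. The sampler targets exactly the same `log_posterior()` that the
oracle tests verify term by term; the published analysis used NUTS, and any
valid MCMC scheme targeting this density estimates the same posterior.

Chain seeds derive deterministically from the user seed, so identical
calls reproduce identical draws.

## MAP estimation

`map_estimate()` maximizes the posterior on an unconstrained
reparameterization (log scale for $\alpha$, $\sigma$, $\tau$) with
multiple restarts seeded from posterior draws, and **without** the
change-of-variables Jacobian — the target is the mode of the stated
density, not of a transformed one.

One subtlety dictates the implementation: the *joint* density of any
hierarchical Gaussian model is unbounded along the ridge $\tau_j \to 0$,
$\lambda_{j,k} \to \nu_j$ (the $-K\log\tau$ term diverges), so "the joint
mode" is not a usable estimator and chasing it is numerically
ill-conditioned (curvature $1/\tau^2$). The optimizer therefore runs on
the **marginal** posterior of $(\alpha, \beta, \sigma, \tau)$ with
$\lambda$ integrated out exactly (each cell's marginal likelihood is
Gaussian with covariance $\sigma^2 I + \tau^2 J$, evaluated via
Sherman–Morrison). This surface is bounded and smooth; $\hat\tau = 0$ on
the boundary is a legitimate result. The reported $\lambda$ estimates are
their conditional posterior means at the optimum, and the returned
`log_posterior` value is the joint density there (with $\tau$ floored at
$10^{-8}$ to keep it finite when $\hat\tau = 0$).

## HPD intervals and contrast point estimates

`hpd_interval()` returns the shortest contiguous window of the sorted
draws containing $\lceil 0.95\, n\rceil$ points; when several windows tie,
the left-most is returned so output is deterministic. Derived contrasts
(`derived_contrasts()`) are computed per draw — element-wise sums and
differences of Markov chain samples — and summarized by a 95% HPD plus a
point estimate: the transform of the joint MAP when one is supplied
(MAP-consistent), otherwise the kernel-density mode of the derived sample.

## PSIS-LOO

No LOO library is assumed: `psis_loo()` implements Pareto-smoothed
importance sampling from first principles. Per observation, the largest
$\lceil\min(0.2S, 3\sqrt S)\rceil$ importance ratios are replaced by
expected order statistics of a generalized Pareto distribution fitted to
the tail with the Zhang–Stephens profile-posterior estimator (with the
usual weak shape regularization toward 0.5), truncated at the raw maximum.
Shapes $k > 0.7$ are flagged per observation. Models are ranked by
`elpd_loo`; pairwise differences against the top model carry the paired SE
$\sqrt{n\,\mathrm{var}(\Delta_i)}$. Self-comparison is exactly zero and
the ranking is invariant to observation order (both are tested).

## The synthetic world

`synthetic_config()` states the experiment the generator emulates, and its
defaults *are* that world, not tuning dials:

| parameter | default | meaning |
|---|---|---|
| `n_replicates` | 6 | replicate microcosms per copper level |
| `n_isolates` | 24 | isolate slots per type per microcosm |
| `dropout_prob` | 0.089 | i.i.d. Bernoulli slot loss, reproducing the observed shortfall from 1,152 possible to roughly 1,049 assayed isolates |
| `alpha` | (0.49, 0.70) | baseline mean score, community / SBW25 |
| `beta` | (+0.045, −0.040) | copper effect per type |
| `sigma` | (0.10, 0.07, 0.03, 0.035) | residual SD per group |
| `tau` | 0.02 | replicate-level SD |
| `assay_noise_sd` | 0.01 | additive absorbance noise on simulated CAS reads |
| `a_ref` | 0.6 | reference absorbance |
| OD draw | U(0.3, 1.2) | no OD distribution is stated anywhere; this range keeps the CAS inversion well-conditioned |

Dropout as i.i.d. Bernoulli is an assumption (the experiment only records
"fewer than 24 isolates" for some replicates, not why); whole-microcosm
loss is tolerated downstream (the $\lambda$ matrix is ragged-capable) but
not generated by default. Genus labels are drawn from a configurable
categorical distribution with optional per-genus mean offsets; the
default offsets are zero so that the generative process is *exactly* the
hierarchical model — genus structure is opt-in for effect-size tests
because no genus-level generative detail is stated. Community and SBW25
rows with the same copper level and replicate share a microcosm ID,
mirroring the coculture arm that the hierarchical model analyzes.

What a green test on this world establishes: that the estimators recover
the stated generative structure at the stated scale. What it does not
establish: robustness to non-Gaussian trait distributions, plate/batch
effects in the CAS assay, non-random isolate loss, or taxon abundance
dynamics — none of which the generator emulates.

## Other numerical conventions

* **CAS standardization** shifts scores by the dataset minimum only when
  that minimum is negative; clean datasets keep their absolute scale. The
  shift scope is the whole analysis dataset, not the plate. OD values at
  or below 0 are errors; values below 0.05 warn (near-zero OD makes the
  score ill-conditioned).
* **Cohen's d** uses the classic $(n-1)$-weighted pooled SD.
* **Spearman p-values**: exact permutation enumeration for $n \le 7$;
  seeded Monte Carlo permutation (20,000 draws) for $n = 8, 9$, where full
  enumeration is needlessly slow in interpreted code; asymptotic
  *t* approximation above. $S$ is reported with midrank ties and is
  non-integer under ties. The statistic and $\rho$ are exact in all cases;
  only the p-value convention varies.
* **Factorial model reduction** tests the interaction against the additive
  model, then each main effect by deletion from the additive model;
  marginal means pool cell predictions with equal weight and use
  *t* quantiles on the residual df of the model retained after reduction
  (interaction dropped at $p \ge 0.05$).
* **Genus retention** for effect-size screens defaults to at least 3
  isolates per copper treatment ("commonly occurring" is not a stated
  threshold); the high-baseline flag splits at a control mean of 0.55.
* Time is in hours throughout; week-long competition assays must be
  converted before computing Malthusian parameters.

## Limitations

* The sampler and MAP routine are specific to this model family; this is
  not a general-purpose probabilistic programming layer.
* MCMC-derived quantities (HPD bounds, LOO SEs) carry Monte Carlo error of
  a few percent at the default draw count; raise `iterations` for tighter
  summaries.
* The factorial marginal-means model covers the 2×2 design only — no
  general contrast algebra, no mixed-model REML.
* Real-data ingestion supports arbitrary column names via `column_map`,
  but the published dataset itself is not bundled; all shipped checks run
  on the synthetic world.
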