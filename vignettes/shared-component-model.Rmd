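---
title: "Joint spatial modelling of two binary survey outcomes with a shared component"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint spatial modelling of two binary survey outcomes with a shared component}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharedcomp)
```

## The model

`sharedcomp` fits a shared-component disease-mapping model (in the
Knorr-Held–Best tradition) for two correlated binary outcomes recorded on
individuals nested in districts — the motivating application is modern
contraceptive use (`mcu`) and sexual health knowledge (`shk`) among women
in household surveys. For woman $i$ in district $j$ and outcome
$d \in \{1, 2\}$,

$$
y_{ijd} \sim \mathrm{Bernoulli}(P_{ijd}), \qquad
\mathrm{logit}(P_{ijd}) \;=\; \alpha_d + x_{i}^\top \beta_d
  + \sigma_d V_j + S_{jd},
$$

with per-outcome intercepts $\alpha_d$ and coefficient vectors $\beta_d$
(reference-category dummy coding), one latent spatial field $V$ **shared**
by both outcomes, and outcome-specific fields $S_d$. The loading
$\sigma_d$ sets how strongly the shared field acts on each outcome. The
Bernoulli log-likelihood is evaluated in the exponential-family form
$y\eta - \log(1 + e^\eta)$, which is numerically stable for any $\eta$.

The default **reciprocal parameterization** sets $\sigma_1 = \delta$ and
$\sigma_2 = 1/\delta$. The product $\sigma_d V_j$ is invariant to
rescaling $(\delta V, \delta)\mapsto(cV, \delta/c)$, so *some* constraint
is needed for $\delta$ and the scale of $V$ to be separately identified;
the reciprocal form is the standard resolution and makes
$\delta$ interpretable as the *relative* strength of the shared component
on outcome 1 versus outcome 2. A `free` mode with two independent
log-normal loadings exists for sensitivity analysis but is weakly
identified and flagged as such.

### Priors

* **Fields** $V, S_1, S_2$: intrinsic CAR (Besag) priors on the district
  adjacency graph,
  $\pi(s \mid \tau) \propto \exp\{-\tfrac{\tau}{2}\sum_{i \sim j}(s_i - s_j)^2\}$.
  The density is improper — rank-deficient by one per connected graph
  component — so the package works with the rank-aware log-density
  $\tfrac{n-c}{2}\log\tau - \tfrac{\tau}{2}\,s^\top(D-A)\,s$ and enforces a
  per-component sum-to-zero constraint. The $\tau$-dependent part of the
  normalising constant must be kept (and is), otherwise posteriors for
  $\tau$ are wrong.
* **Scaling.** Marginal ICAR variances depend on the graph, so a precision
  prior calibrated on one map means something different on another. All
  fields use the *scaled* ICAR convention: the precision is
  $c\,\tau\,(D-A)$ with $c$ the geometric mean of the diagonal of the
  constrained generalized inverse of $D-A$ (`scale_factor()`), making the
  geometric-mean marginal variance $1/\tau$ on every graph and the PC
  priors comparable across countries/maps.
* **Spatial precisions** $\tau_V, \tau_{S_1}, \tau_{S_2}$:
  penalised-complexity priors, the Type-2 Gumbel density
  $\tfrac{\lambda}{2}\tau^{-3/2}e^{-\lambda/\sqrt{\tau}}$ with
  $\lambda = -\log(\alpha)/U$, defined by the tail condition
  $P(1/\sqrt{\tau} > U) = \alpha$. Default $(U, \alpha) = (1, 0.01)$: the
  prior says a field standard deviation above 1 (on the log-odds scale)
  has probability 0.01. A literal rate $\lambda$ can be set directly via
  `pc_prior = list(lambda = ...)` for sensitivity analysis.
* **Loading**: $\log\delta \sim N(0, 1/0.1)$ (log-normal with mean 0 and
  precision 0.1), symmetric between the two outcomes on the log scale.
* **Fixed effects and intercepts**: independent
  $N(0, 1/\tau_\beta)$ with $\tau_\beta = 0.001$ by default (sd
  $\approx 31.6$ log-odds units — weakly informative).

### Outcome coding

Modern contraceptive use is already binary (1 = modern method user).
Knowledge is commonly graded Poor/Moderate/Good; the Bernoulli model needs
a dichotomy, so `dichotomize_knowledge()` codes Good = 1 by default, with
a configurable cut at Moderate (`knowledge_cut = "moderate"`). Records
with missing covariates or outcomes are dropped on load with a reported
count (complete-case analysis).

Survey weights are carried through the data model and used by the
descriptive statistics (`weighted_prevalence()`, `weighted_crosstab()`);
the Bayesian model itself is fit unweighted. This is a deliberate,
documented choice: design-weighted Bayesian binary regression has no
single standard form, and the descriptive layer is where the weights
matter for the published-style tables.

## Inference

Posterior computation is adaptive Metropolis-within-Gibbs MCMC
(`fit_mcmc()`), written in C++ for speed:

* $(\alpha_d, \beta_d)$ move as one block per outcome with a Haario-style
  adaptive proposal covariance (running covariance of the visited states,
  scale $2.38/\sqrt{q}$, Robbins-Monro tuned to acceptance 0.35). Block
  moves matter here: dummy-coded designs make the intercept and
  coefficients strongly correlated a posteriori, and coordinate-wise
  updates mix an order of magnitude slower.
* $V$ and $S_d$ use single-site random walks (target acceptance 0.44)
  followed by per-component recentering — the standard identifiability
  projection for the improper ICAR, as in mainstream CAR packages.
  Isolated districts carry no spatial information and stay at 0.
* $\log\delta$ and the $\log\tau$'s use scalar random walks (the log-scale
  Jacobian is included).
* All adaptation happens during burn-in only; the post-burn-in kernel is a
  fixed, valid MCMC.

Chain 1 starts at a neutral state (zeros; $\delta = \tau = 1$). Later
chains start overdispersed: $N(0,1)$ perturbations on location parameters,
log-scale sd 0.5 on $\delta$ and the $\tau$'s, and a fresh ICAR draw for
$V$, each under a documented seed offset (`seed + 1000(k-1)`). Literal
draws from the $\tau_\beta = 0.001$ prior would start chains at $|\beta|
\sim 30$, where the likelihood is saturated and finite chains cannot
recover; moderate overdispersion preserves the purpose of multiple chains
(detecting non-convergence via split-R-hat) at realistic run lengths.

Summaries (`summarize_chains()`) are pooled posterior means, sds and
equal-tailed 95% credible intervals, split-R-hat, and a batch-means
effective sample size (25 batches per chain; between-chain disagreement
inflates the Monte-Carlo variance estimate, which is the conservative
direction). Coefficient rows also carry the odds-ratio view: summaries of
the exponentiated draws, with OR quantiles equal to exponentiated
coefficient quantiles (quantiles commute with monotone transforms).
`odds_ratio_table()` formats these in the reporting convention of
adjusted-OR tables (reference rows print a literal `1`; other rows
`OR (q2.5, q97.5)` at three decimals, round-half-even).
`district_effect_surface()` reports, per district and outcome, the
posterior of $\exp(\sigma_d V_j)$ (shared), $\exp(S_{jd})$ (specific) and
their product (total) — the tabular form of the usual posterior-effect
choropleths, keyed by district label for downstream mapping.

### Validation oracle

`quadrature_oracle()` integrates the *same* joint log-posterior (the pure
R `joint_log_posterior()`, independent of the C++ sampler) over a dense
grid for up to three free scalar parameters, with midpoint-width weights
for non-uniform (e.g. log-spaced) grids and a boundary-mass guard
(normalized mass on the grid edge must be below $10^{-6}$, otherwise it
errors and asks for a wider grid). On small instances the MCMC moments are
required to match the quadrature within tight absolute tolerances; this is
the package's substitute for trusting any single sampler implementation.

## The synthetic data generator

`simulate_dataset()` draws from the model's own generative process, so
every pipeline stage is testable with known ground truth:

* a district lattice (default a 6×5 rook-adjacency grid — 30 districts,
  a typical national district count at DHS scale);
* $V \sim$ scaled ICAR$(\tau_V)$, $S_d \sim$ scaled ICAR$(\tau_{S_d})$;
* seven categorical covariates (age group, education, marital status,
  mass-media exposure, residence, community literacy, community
  socio-economic level) drawn independently with configurable category
  probabilities (uniform by default);
* outcomes from the linear predictor above; weights constant 1 by default
  or log-normal to exercise the weighted descriptives.

Presets encode published prevalence extremes as calibrations:
`"uganda-like"` sets both intercepts to $\mathrm{logit}(0.27)$ (the
highest country-level modern contraceptive use among the surveyed
populations, 27%), `"chad-like"` to $\mathrm{logit}(0.01)$ (the 1% low
end). These are generator settings, not reproduction claims.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real survey data: two-stage cluster sampling and
non-response (weights here are iid, not design weights), dependence
between covariates (education × residence correlation, say), item-level
disability screening logic, and real district adjacency irregularities
beyond what grid and user-supplied graphs cover. Recovery results on
synthetic data demonstrate the *inference machinery* is correct, not that
the model is adequate for any particular survey.

## Numerical choices and edge cases

* `bernoulli_loglik` uses $\max(\eta,0) + \log(1+e^{-|\eta|})$; no
  overflow for $|\eta|$ up to (and beyond) 700.
* Sum-to-zero is enforced per connected component by centering; an input
  field violating the constraint beyond tolerance is an error, not a
  silent fix.
* `scale_factor` excludes isolated districts from the geometric mean (they
  have no spatial variance to scale) and errors on a graph with no
  adjacencies at all.
* Degenerate descriptive tables (a margin with one observed level) flag
  the chi-square as undefined rather than erroring the pipeline; p-values
  below $10^{-3}$ print as `<0.001` with the exact value retained in
  machine-readable output.
* An outcome with zero variance in the data produces a warning and a
  prior-dominated fit for that outcome's coefficients, not a failure.
* Equal-tailed credible intervals (not HPD), matching the usual reporting
  convention of 95% credible intervals in applied spatial epidemiology.

## Problem sizes used in the test suite

The validation suite runs at deliberately modest scales chosen to exercise
every property while keeping a laptop-friendly runtime: ICAR algebra on
2×2 … 5×5 grids against dense-matrix oracles; sampler-vs-quadrature
agreement on a 3-district path with 60 records (long chains, since the
instance is tiny); reduction to logistic regression on 5,000 records
against the IRLS MLE; and a 20-replicate recovery study on the default
30-district grid with 100 records per district, true $\delta \in
\{0.5, 1, 2\}$ and coefficients in $[-1, 1]$, requiring pooled 95%
interval coverage of at least 80% and posterior-mean/truth correlation of
the shared field above 0.5.

## A worked example

```{r example, eval = FALSE}
library(sharedcomp)

# simulate a 30-district study with a strong shared component
cfg <- sim_config(graph = grid_graph(6, 5), n_per_district = 100,
                  schema = default_schema()[c("education", "residence")],
                  alpha = c(-0.4, 0.2), delta = 2, tau_V = 1,
                  tau_S = c(4, 4), seed = 1)
ds <- simulate_dataset(cfg)

spec <- model_spec(covariate_schema = cfg$schema)
fit <- fit_mcmc(ds$records, ds$graph, spec,
                chain_config(n_iter = 6000, burn_in = 2000, seed = 2))

sm <- summarize_chains(fit)
odds_ratio_table(sm, spec$covariate_schema)
head(district_effect_surface(fit))
cor(sm$mean[match(paste0("V.", ds$graph$node_ids), sm$param)],
    ds$truth$state$V)
```

## Known limitations

* The inference engine is MCMC; no nested-Laplace approximation is
  provided. For very large surveys (hundreds of thousands of records) run
  times grow linearly in $n$.
* The knowledge outcome is modelled as a dichotomized Bernoulli variable;
  no ordinal (3-level) likelihood.
* No spatio-temporal extension, covariate selection, or model-comparison
  criteria (DIC/WAIC).
* Adjacency must be supplied (or generated as a grid); the package does
  not derive contiguity from shapefiles and does not render maps — the
  district-effect table is the mapping interface.
* In `free` loading mode the shared-field scale is only weakly identified;
  the reciprocal default is recommended for reporting.
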