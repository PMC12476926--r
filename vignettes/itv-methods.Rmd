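---
title: "Methods: ITV, environmental heterogeneity, and how itvar validates itself"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ITV, environmental heterogeneity, and how itvar validates itself}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`itvar` quantifies intraspecific trait variation (ITV) of log-transformed
functional traits and relates it to environmental heterogeneity at the site
scale (spatial terrain roughness, temporal rainfall seasonality) and at the
range scale (the breadth of environmental conditions across a species'
occurrence records). This vignette is the package's own account of the
models, the choices behind them, and what the validation suite does and
does not establish.

## 1. The ITV* statistic

Trait values in forest inventories are approximately log-normal, so all
variances are taken on natural-log values. For a cell (one species at one
site) with $n$ individuals, ITV is the denominator-$n$ variance of the log
values and

$$\mathrm{ITV}^* = \frac{n}{n-1}\,\mathrm{ITV},$$

i.e. the unbiased sample variance of the logs. Models use
$\log \mathrm{ITV}^*$ as the response. Consequences worth noting:

- **Reciprocal invariance.** $\mathrm{Var}(\log 1/x) = \mathrm{Var}(\log x)$,
  so a trait and its inverse (LMA vs specific leaf area) give the same
  ITV\*. The test suite checks this to $10^{-12}$ on random vectors.
- **Scale invariance.** Unit changes shift the logs by a constant and leave
  ITV\* untouched.
- **Base of logarithms.** Natural logs throughout. The base only shifts
  $\log \mathrm{ITV}^*$ by a constant, which intercepts absorb.
- **Degenerate cells.** A cell whose values are all identical has
  $\mathrm{ITV}^* = 0$ and no defined log; such cells are excluded from
  model input with a warning. They have probability zero under the
  generator and essentially never occur in continuous trait data.

**Inclusion thresholds.** Species qualify with at least `min_sites = 4`
sites holding at least `min_per_site = 6` individuals each — the strict
reading of "more than 3 sites, more than 5 individuals". Both are exposed
as arguments of `filter_included()` because the inclusive reading
(≥ 3 / ≥ 5) is equally defensible; the site-count rule is evaluated on
qualifying cells only, since cells below the per-site minimum cannot
contribute a reliable variance in the first place.

## 2. Environmental variability metrics

**Terrain roughness (spatial).** Per cell of a digital elevation model, the
mean absolute elevation difference to its 8-neighborhood; the site metric
is the mean over valid cells. Edge cells use only their existing neighbors
(no padding, no reflection): padding conventions invent relief that is not
in the data. Nodata cells are excluded on both sides of every difference.
Closed forms used as oracles: a constant grid has TRI 0; a ramp rising $s$
per cell has interior TRI $6s/8$; iid Gaussian noise with sd $\sigma$ has
expected interior TRI $2\sigma/\sqrt{\pi}$ (the mean absolute difference of
two independent normals). The implementation is vectorized over the eight
shifts and is checked against a brute-force double loop.

**Rainfall seasonality (temporal).** $100\times$ the sample ($n-1$)
standard deviation of the twelve mean monthly precipitation values over
their mean. The $n-1$ convention matches the Bessel convention used
elsewhere in the package; with $n=12$ fixed it is a constant factor and
does not affect comparisons between sites.

**Range breadth.** Per species and environmental attribute, the width of
the central 95% interval across occurrence records, using
linear-interpolation quantiles (`stats::quantile` type 7) — the default of
the mainstream statistics stacks, stated here because the quantile type is
otherwise a silent degree of freedom. The central-quantile reading (rather
than a parametric confidence interval of the mean) is the one consistent
with "range" semantics, and is what the generator's truth values
($0.95\,w$ for a uniform niche of width $w$) assume. Note that
interpolated quantiles are *not* exactly invariant to duplicating a finite
record set — the interval widens slightly toward the empirical range as
copies accumulate — so the duplication test asserts the widening direction
and the exact three-copy value instead of equality. Geological breadth is
the count of distinct geology classes
({volcanic, limestone, alluvial, ultramafic} by default, extensible).

## 3. The within-site hierarchical model

$$\log \mathrm{ITV}^*_{si,sp} = \beta_0 + \beta_{1,sp} + \beta_{2,sp}\,
\mathrm{env}_{si} + \epsilon / n_{si,sp}, \qquad
\beta_{1,sp}\sim N(\mu_1,\sigma_1),\;
\beta_{2,sp}\sim N(\mu_2,\sigma_2),\;
\epsilon\sim N(0,\tau)$$

with uniform$(0,10)$ priors on $\sigma_1,\sigma_2,\tau$ and $N(0,1)$ priors
on means and intercept. Design choices that the formulation leaves open:

- **Residual scaling.** Dividing the residual draw by $n$ makes the row
  residual sd $\tau/n$. That is the literal reading of the model statement
  and the default (`error_scaling = "sd_over_n"`); the common alternative —
  variance shrinking like $1/n$, sd $\tau/\sqrt{n}$ — is one switch away
  (`"sd_over_sqrt_n"`). Under the default, the implied generalized
  least-squares weights are $n^2$, which the validation suite exploits (see
  §6).
- **Identifiability.** $\beta_0$ and $\mu_1$ enter only as a sum, so the
  default fixes $\beta_0 \equiv 0$ and reports $\mu_1$ as the intercept;
  `literal_intercept = TRUE` restores the redundant parameterization for
  sensitivity checks (both parameters then lean on their priors and only
  $\beta_0+\mu_1$ is interpretable — a test asserts exactly that).
- **Predictor standardization.** The environmental metric is z-scored
  across the distinct site values, so the $N(0,1)$ priors on $\mu_2$ are
  weakly informative regardless of whether the predictor arrives as a CV
  percentage (tens) or a roughness in meters (units). Raw-scale fitting is
  available (`standardize = FALSE`).
- **Sampler.** JAGS (rjags), 4 chains × 2000 sampled iterations after 1000
  adaptation/burn-in by default; per-chain seeds derive deterministically
  from one master seed, so fits are exactly reproducible. Uniform priors
  are hard bounds; split-$\widehat{R}$-style diagnostics come from
  `coda::gelman.diag`, and any $\widehat{R} > 1.01$ raises a warning, not a
  failure, with the draws still returned.

A species slope (and the community slope $\mu_2$) is labelled positive or
negative when its central 95% credible interval excludes zero,
nonsignificant otherwise.

## 4. The range regression

Per species, the across-site $\log \mathrm{ITV}^*$ (all of a species' data
pooled; the across-site $n$ is the sum of the cell $n$'s) — or the species
mean log trait for the conservative-strategy variant — is regressed on the
standardized range breadths. The fitting package the original analysis
tradition uses is a thin Bayesian layer over least squares, so the priors
here are chosen to make that limit exact and testable: independent
$N(0, 2.5\,\mathrm{sd}(y)/\mathrm{sd}(x_j))$ priors on slopes, flat
intercept. Point estimates are the analytic conditional posterior mean at
the OLS residual variance (deterministic); credible intervals (90%
headline, 95% alongside) come from a Gibbs sampler over coefficients and
residual variance. With the prior scale inflated the point estimates match
OLS to $10^{-5}$, which the suite asserts.

**AIC and selection.** AIC $= 2k - 2\log L$ with $\log L$ the Gaussian
log-likelihood at the point estimates under the ML residual variance and
$k$ counting coefficients, intercept and residual sd. Backward elimination
greedily drops the predictor whose removal lowers AIC most, stopping when
no removal lowers it; the trace keeps every candidate AIC, and
leave-one-out "AIC without X" diagnostics are reported around the final
model. An exhaustive all-subsets search (`exhaustive_select()`, feasible to
8 predictors) is the built-in cross-check. Two statistical facts are worth
stating plainly, because the test suite was designed around them rather
than against them:

- Greedy backward elimination is *not* guaranteed to find the all-subsets
  AIC optimum; with independent predictors and a few hundred observations
  the two agree essentially always (the suite checks agreement on 50
  simulated datasets at $n = 200$), but with small $n$ and correlated
  predictors occasional disagreement is expected behavior, not a bug.
- AIC-based stepwise keeps a pure-noise predictor whenever its chi-square
  improvement exceeds 2, which happens with probability
  $P(\chi^2_1 > 2) \approx 0.157$ per predictor. Exact support recovery
  ("the final set is precisely the active predictors") therefore caps near
  $0.84^{m}$ with $m$ null predictors and is *not* a property any
  seed or sample size can buy. The end-to-end recovery check accordingly
  asserts what selection consistency can deliver: the active predictor is
  retained and its 90% interval excludes zero.

VIF is computed as the diagonal of the inverse predictor correlation
matrix — algebraically $1/(1-R^2_j)$ from regressing predictor $j$ on the
rest, which is exactly the oracle the tests recompute. The mean-trait model
reuses the identical design and selection machinery, and the
mean-versus-ITV Pearson correlation is evaluated at the species scale
(pooled mean of log trait against log across-site ITV\*), with the
two-sided $p$ from the $t$ distribution on $n-2$ degrees of freedom.

## 5. What the generator emulates — and what it does not

`simulate_traits()` inverts the within-site model exactly: species effects
from their hyperdistributions, cell-level true $\log \mathrm{ITV}^*$ with
$\epsilon/n$ noise under the same error-scaling switch as the fit, then
individual log values drawn at that variance and exponentiated. Defaults
are the study-shaped conditions: 33 species × 8 sites, each species at a
random ≥ 4 sites, cell sizes Poisson(12) truncated at 6 (the unbalanced
design that motivates the Bessel correction and the $n$-scaled error),
community mean log ITV\* of $-3$ (log-trait sd ≈ 0.22, a realistic
magnitude for wood density), $\sigma_1 = 0.3$, $\sigma_2 = 0.2$,
$\tau = 0.5$, and site variability values spanning 25–60, the span of
rainfall-CV percentages across the packaged site table. Species mean log
traits are $N(0,1)$ nuisance draws: ITV quantities are location-free, so
their value never matters.

`simulate_occurrences()` draws each species' attribute values uniformly on
a niche of known width (truth: $0.95\,w$) and geology labels from a random
class subset. `simulate_coupled_itv_range()` chains the two: standardized
range predictors first, species-level target $\log \mathrm{ITV}^*$ from
the linear model (default: one active predictor, PET range, coefficient
0.5, residual sd 1, 200 species), then observations realizing that pooled
variance. All randomness flows from a master seed through named substreams,
so each component is independently reproducible.

Deliberate idealizations — and therefore the limits of what green tests
prove about field data: individuals are exchangeable within cells (no
ontogeny, no microhabitat structure); cell noise follows the fitted model's
own convention, so recovery tests are well-posed under either error
scaling but cannot adjudicate *between* the conventions; niches are
uniform boxes, not correlated response surfaces; occurrence records carry
no spatial autocorrelation or sampling bias; and measured log sample
variances add $\chi^2$ sampling noise (sd $\approx \sqrt{2/(n-1)}$) on top
of the model's $\tau/n$ term, a mild, acknowledged misspecification that
the calibration checks absorb.

## 6. Validation design and problem sizes

The suite validates each layer against an independent route, at sizes
chosen to keep the full run in minutes on one core:

- **Exact oracles** ($<10^{-10}$): ITV\* vs a two-pass $n-1$ variance
  (1000 random vectors), TRI vs a brute-force neighborhood loop and its
  closed forms (200×200 noise grid for the $2/\sqrt{\pi}$ expectation),
  type-7 quantiles recomputed by hand, VIF vs leave-one-out regressions,
  the AIC identity on every fit.
- **Parameter recovery**: with $\mu_2 = 0.8$ under the study-shaped
  conditions above (30 species × 8 sites, $n \approx 12$), the posterior
  mean of $\mu_2$ lands within ±0.15 of truth and the 95% interval covers
  truth in ≥ 90% of 20 replicate seeds (4 chains × 2000 iterations each).
- **Calibration**: under $\mu_2 = 0$, the 95% interval covers zero in
  ≥ 90 of 100 replicates at reduced sampler settings; under a null range
  regression, 90% intervals cover zero at the nominal rate.
- **Degenerate-limit cross-checks**: with no species-level spread the
  hierarchical posterior means match $n^2$-weighted least squares within
  0.02; with inflated priors the range regression matches OLS; noiseless
  responses are recovered exactly.
- **End-to-end**: the coupled generator's active predictor is retained and
  significant in ≥ 90% of 50 replicates; the full `paper_scale` pipeline
  run is byte-identical under a repeated seed.

## 7. Known limitations

- The hierarchical model treats site environmental metrics as known
  constants; measurement error in a DEM-derived roughness or an
  interpolated rainfall climatology propagates nowhere.
- The $\tau/n$ residual convention is aggressive for very large cells
  (residual sd $\to 0$ like $1/n$ while the $\chi^2$ noise floor of a log
  sample variance shrinks only like $1/\sqrt{n}$); interval coverage for
  the slope hypermean remains near nominal at the study's cell sizes, but
  applications with $n$ in the hundreds should prefer
  `error_scaling = "sd_over_sqrt_n"` and compare.
- Stepwise AIC selection inherits its classical caveats (see §4); the
  reported full-model fit and the selection trace are always emitted so a
  reader can bypass the final model entirely.
- No spatial autocorrelation between sites, no phylogenetic signal in
  species effects, no multi-trait covariance: traits are analyzed
  separately.
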