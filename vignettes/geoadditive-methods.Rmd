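---
title: "Bayesian geo-additive modelling of pooled survey prevalence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian geo-additive modelling of pooled survey prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starlogit)
```

## The problem and the model

Household surveys such as the DHS and MICS record, for each surveyed
mother, whether each of her 0–14-year-old daughters has undergone female
genital mutilation/cutting (FGM/C). Pooling several survey waves buys
sample size and a time axis, but the data are doubly dependent: daughters
of one mother share her covariates and unobserved norms, and neighbouring
states share culture and practice. `starlogit` implements the structured
additive (STAR) logistic model built for exactly this situation. For girl
$i$ in state $s_i$:

$$\mathrm{logit}(p_i) = \eta_i = f_{str}(s_i) + f_{unstr}(s_i) + f(\text{year}_i)
 + f(\text{age}_i) + z_i'\omega + \text{survey}_i + \xi_{s_i,\text{year}_i},$$

with $y_i \sim \mathrm{Bernoulli}(p_i)$ and:

* $f_{str}$ — spatially **structured** state effect with an intrinsic
  Gaussian Markov random field (ICAR) prior: conditionally, each state is
  normal around the average of its neighbours with variance
  $\tau^2_{str}/N_s$. In penalty form the prior precision is the graph
  Laplacian $K$ ($K_{ss} = N_s$, $K_{rs} = -1$ for neighbours), which has
  rank $S-1$ on a connected graph.
* $f_{unstr}$ — iid $N(0, \tau^2_{unstr})$ **unstructured** heterogeneity,
  capturing state-specific effects that do not diffuse across borders.
* $f(\text{age})$ — a Bayesian P-spline: cubic B-splines on equidistant
  knots whose coefficients follow a second-order random walk (RW2)
  $\beta_m = 2\beta_{m-1} - \beta_{m-2} + u_m$, i.e. the penalty is the
  summed squared second difference.
* $f(\text{year})$ — the same RW2 penalty over the six observed survey
  years.
* $z_i'\omega$ — treatment-coded categorical fixed effects (education,
  residence, mother's own cut status, support for continuation) with flat
  priors; posterior odds ratios read against the reference level.
* survey — a DHS/MICS fixed effect (DHS reference) absorbing systematic
  differences between the two survey families.
* $\xi$ — a state-by-survey-year interaction, either iid
  $N(0, \tau^2_\xi)$ (model m6) or RW2-smooth in time within each state
  (model m5).

All variance parameters get conjugate inverse-gamma IG$(a, b)$ hyperpriors,
default $a = 1$, $b = 0.0005$ (diffuse).

### Identifiability

Every non-fixed function is centred to mean zero over the observed data,
with the removed mean absorbed into the intercept. This is essential:
the ICAR prior is improper (rank-deficient), and the structured and
unstructured effects are only separately interpretable under the
centring convention. The sampler re-centres each non-fixed block after
every update; because all such design matrices here have unit row sums
(one-hot indicators, B-spline partitions of unity), the operation is exact
and leaves the likelihood untouched. `sample_igmrf()` similarly draws the
intrinsic field by spectral decomposition, dropping the null-space
direction and re-centring.

## Posterior computation

Inference is MCMC with Metropolis–Hastings block updates using iteratively
weighted least squares (IWLS) proposals. For a block with design $X$,
penalty $K$ and variance $\tau^2$, the proposal at the current state is
$N(m, P^{-1})$ with $P = X'WX + K/\tau^2$, $m = P^{-1}X'W\tilde y$, where
$W = \mathrm{diag}(p(1-p))$ (floored at $10^{-6}$ for numerical safety)
and $\tilde y$ is the IWLS working response built from the partial
residual of the block. The acceptance ratio uses the exact Bernoulli
likelihood, the (improper) Gaussian penalty prior, and the reverse
proposal density rebuilt at the proposed state. Fixed effects are updated
as one joint block under a flat prior. Variances are Gibbs-updated from
the conjugate full conditional
$\tau^2 \mid \beta \sim \mathrm{IG}(a + \mathrm{rank}(K)/2,\; b + \beta'K\beta/2)$.

The default schedule is 20,000 iterations, 4,000
burn-in, thinning 20 (800 stored draws). The update order is fixed →
smooths → spatial → interaction → variances, deterministic for exact
reproducibility under a seed; a single chain is the default.

Two exact algebraic shortcuts keep the sampler fast in plain R without
changing a single draw: for one-hot designs $X'WX$ is diagonal with the
grouped weight sums, and for designs whose rows take few distinct values
(covariate patterns, unique ages) $X'WX = X_u'\,\mathrm{diag}(G'w)\,X_u$
with $G$ the pattern indicator. Both paths were verified to produce
bit-identical chains to the naive implementation.

## Model assessment and summaries

* **DIC** $= \bar D + p_D$ with $\bar D$ the posterior mean girl-level
  deviance $-2\log L(\eta)$ and $p_D = \bar D - D(\bar\eta)$; since
  $\eta$ is linear in the coefficients, $\bar\eta$ is evaluated at the
  posterior-mean coefficients. A negative $p_D$ is reported with a
  warning, never hidden. The nested suite m1–m6 (and single-year starred
  variants) is ranked by DIC; ties break toward the simpler model, with
  no ΔDIC threshold.
* **Posterior odds ratios**: the posterior mean of $e^\beta$ with
  2.5/97.5% quantiles (and $e^{\bar\beta}$ alongside, since the two
  summaries differ); reference rows are emitted as 1.00.
* **Predicted prevalence**: per draw, $p = e^\eta/(1+e^\eta)$ averaged
  over the girls of each state, then summarised across draws. States with
  no observations are reported at the covariate-reference profile from
  intercept + spatial effects only and flagged `borrowed`.
* **Deviance map**: the grouped binomial deviance
  $D = 2\sum\{y_k\log(y_k/\hat\mu_k) + (n_k-y_k)\log((n_k-y_k)/(n_k-\hat\mu_k))\}$
  per state at the posterior-mean prevalence. For girl-level 0/1 data the
  saturated likelihood is 0, so the DIC deviance is simply $-2\log L$; the
  grouped form is reserved for the per-state map where $n_k$ trials make
  it meaningful.
* **Significance maps**: a state is classified *high* if the 2.5%
  quantile of its spatial effect exceeds 0, *low* if the 97.5% quantile is
  below 0, else *nonsignificant* — the black/white/grey convention.
  Whether the total effect $f_{str}+f_{unstr}$ (default) or the
  structured component alone is classified is switchable; conventions
  vary in the disease-mapping literature. No multiplicity adjustment is
  applied across states (raw 95% intervals), a documented caveat.
* **Moran's I** over the binary contiguity graph tests for clustering of
  per-state values, with the analytic normality approximation
  ($E[I] = -1/(S-1)$) or a permutation Monte-Carlo p-value
  $(1+k)/(1+n_{sims})$, which can never be zero. Binary unstandardised
  weights are used throughout — the default for contiguity graphs, and
  the weighting scheme was not otherwise specified. Only the global
  statistic is provided; local (LISA) statistics are out of scope.

## The synthetic world

The real microdata are access-restricted, so the generator emulates their
statistical structure; its defaults are fixed once from reported
national-survey marginal quantities and are not tuning knobs:

* Six waves 2003/2007/2008/2011/2013/2016, DHS and MICS alternating, wave
  shares proportional to the pooled surveys' girl counts (3,281 / 7,768 /
  17,691 / 16,874 / 25,176 / 17,529).
* Girls nest in mothers: a zero-truncated Poisson(1.21) daughters-per-
  mother count reproduces the pooled nesting ratio 88,319 girls /
  51,141 mothers ≈ 1.73, and daughters inherit all mother-level
  covariates — the within-mother dependence the hierarchical model
  exists for.
* Fixed effects default to the logs of pooled-data posterior
  odds ratios: mother cut log 18.153, education Primary log 2.35,
  Secondary log 1.928, Urban log 0.955, MICS log 0.877, support
  Continued log 13.944, Depends log 3.111. The education "None" level is
  not printed in the pooled table; log 2.6 was fixed once, slightly above
  the Primary value, consistent with the 2016-only table's ordering.
* The default intercept −3.7 is the log-odds at the reference profile
  (higher-educated, uncut, continuation-opposing, rural mother) — a
  genuinely low-risk profile. With the default covariate mix this puts
  the marginal prevalence near the reported national ~25%; the
  spec-level check `logit^{-1}(-1.1) ≈ 0.25` is exercised with all other
  effects zeroed.
* Spatial variances $\tau^2_{str} = 0.5$, $\tau^2_{unstr} = 0.05$,
  interaction $\tau^2_\xi = 0.25$ — disease-mapping-typical magnitudes
  giving structured effects of roughly ±1 on the log-odds scale. The age
  and year RW2 paths use increment variances $5\times10^{-5}$ and
  $4\times10^{-3}$, sized so the resulting curves span roughly ±0.8 and
  ±0.4 log-odds (RW2 variance grows cubically in the number of steps,
  hence the small numbers).
* Region assignment is uniform; covariate marginals are round
  national-survey-like mixes. Missingness is MCAR — the neutral choice
  when listwise deletion is the downstream handling. Survey weights are
  Gamma(4,4) normalised to mean 1 and feed **only** the descriptive
  crosstabs; design-weighting a Bayesian hierarchical fit is its own
  methodological question, so the default fit ignores them.

What the generator does **not** emulate: two-stage cluster sampling with
strata/PSU structure, realistic covariate geography (Nigeria's ethnic and
regional composition), or informative missingness. A green recovery test
therefore establishes that the sampler inverts the model's own data
generating process — not that the model is correctly specified for real
survey data.

## Numerical choices and degenerate inputs

* IWLS weights floored at $10^{-6}$; proposal precisions get escalating
  jitter (from $10^{-8}\times$ mean diagonal) with a logged warning if
  Cholesky fails; a non-finite predictor aborts with the offending block
  named.
* The year RW2 treats the six unequally spaced years as equally spaced —
  second differences are unweighted; spacing-aware differences would be a
  one-line change to the penalty.
* The space-time "smooth" interaction (m5) is RW2 over the ordered years
  within each state (penalty $I_S \otimes K_{rw2}$, rank $S(T-2)$):
  temporal autocorrelation within state, with cross-state correlation
  left to $f_{str}$. The source describes an RW2 prior for $\xi$ without
  defining its two-dimensional structure; this is the package's
  resolution of that gap.
* Disconnected graphs are refused by `sample_igmrf()` (per-component
  constraints would be needed) but handled by `mrf_precision()` with
  rank $S - c$.
* Moran's I errors on constant vectors (zero variance) rather than
  returning NaN.
* A constant-or-linear coefficient vector has zero RW2 penalty (the null
  space); the data and the centring convention identify those directions.
* 20 interior knots is the P-spline default (a common default in this
  model family), configurable per model.

## Scaling of the verification suite

The statistical acceptance checks run at desk scale on one CPU: parameter
recovery uses a 6×6 lattice with ~10,000 girls and 4,000 iterations
(the default schedule is 20,000; the shorter chain is compensated by the
near-independence of IWLS proposals), coverage uses 50 light replicates,
and the DIC model-selection study uses ten replicates of a 3×3-lattice
world with 600-iteration chains. Thresholds (3 posterior SDs, Pearson
r ≥ 0.8, coverage in [0.85, 1], m6 winning ≥ 70% of replicates) are
independent of that scaling.

## Known limitations

* Single-site-free but single-chain by default; multi-chain diagnostics
  (R-hat) are not built in.
* No WAIC/LOO; DIC is the single model-comparison criterion.
* No shapefile ingestion or map rendering — graphs come from edge lists
  or `.gra` files; plotting is left to the caller.
* The GRF (geostatistical) prior alternative is deliberately absent: the
  source tried and discarded it, and the MRF's sparsity is what makes
  desk-scale fitting cheap.
* Additional categorical covariates (wealth, ethnicity, region, marital
  status ...) enter exactly like the four defaults: any column with a
  declared reference level can join the fixed block.
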