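# starlogit

Bayesian geo-additive logistic regression for prevalence mapping from
pooled household surveys.

## The problem

Cross-sectional household surveys (DHS, MICS) record binary outcomes —
here, whether a 0–14-year-old girl has undergone female genital
mutilation/cutting (FGM/C) — together with her mother's characteristics,
her state of residence and the survey wave. Pooling six waves across
2003–2016 gives power and a time axis, but observations are not
independent: daughters share mothers, neighbouring states share norms,
and survey families differ systematically. `starlogit` fits the
structured additive regression (STAR) model built for this setting:

    logit(p_i) = f_str(s_i) + f_unstr(s_i) + f(year_i) + f(age_i)
                 + z_i'ω + survey_i + ξ(s_i, year_i)

with an intrinsic Gaussian Markov random field (ICAR) prior on the
structured spatial effect `f_str` (each state conditionally centred on
the mean of its neighbours), iid Gaussian unstructured heterogeneity
`f_unstr`, Bayesian P-splines (cubic B-splines with second-order
random-walk penalties) for mother's age and survey year, treatment-coded
fixed effects `z'ω` with flat priors, and a state-by-year interaction ξ
modelled either as an iid random effect or as an RW2 smooth in time.
Variances carry inverse-gamma IG(1, 0.0005) hyperpriors. Posterior
sampling is Metropolis–Hastings with iteratively weighted least squares
(IWLS) proposals per coefficient block and conjugate Gibbs updates for
variances; model choice uses the DIC over the nested suite m1–m6;
spatial clustering is tested with global Moran's I (analytic and
permutation). Because the real microdata are access-restricted, the
package ships a synthetic-data generator that reproduces the pooled
multi-survey structure (six waves with realistic sample shares,
~1.73 daughters per mother, covariate effects at realistic
odds-ratio magnitudes such as ~18 for a cut mother), so the full
pipeline runs and is tested
end-to-end offline.

## Worked example

```r
library(starlogit)

graph <- make_lattice_graph(6, 6)            # 36 regions, national scale
truth <- draw_truth(graph, seed = 11)        # effects from their priors
data  <- simulate_dataset(truth, graph, n_mothers = 2300, seed = 12)

# spatial clustering of crude regional prevalence
crude <- tapply(data$fgm, data$state, mean)
morans_i_test(crude, graph, method = "analytic")[c("statistic", "p_value")]

# full model: spatial + smooths + covariates + survey + iid interaction
spec  <- model_spec(survey = TRUE,
                    covariates = c("education", "residence",
                                   "mother_cut", "support"),
                    interaction = "iid")
terms <- build_model_terms(data, graph, spec)
fit   <- run_mcmc(data, terms,
                  mcmc_config(n_iter = 1500, burn_in = 500, thin = 5,
                              seed = 13))
dic(fit, data)$dic
posterior_odds_ratios(fit)
head(predicted_prevalence(fit, data, graph))
table(classify_spatial_effects(fit)$class)
```

A run of this example (3,977 girls simulated) prints:

```
$statistic   0.3398        # Moran's I on crude prevalence
$p_value     0.0013
dic          3189          # full-model DIC

   covariate         level   por lower upper
   mother_cut Not cut (ref)  1.00    NA    NA
   mother_cut           Cut 18.19  14.3 22.65

   region label   n prevalence  lower upper borrowed
        1   1.1  82     0.2546 0.1870 0.323    FALSE
        2   1.2  75     0.0833 0.0413 0.133    FALSE

          high            low nonsignificant
             6              6             24
```

The Moran's I of 0.34 (p ≈ 0.001) says the simulated prevalence surface
is spatially clustered, as the ICAR truth makes it. The posterior odds
ratio for a cut mother, 18.19 [14.3, 22.65], brackets the generating
value exp(2.90) ≈ 18.15 (reference rows are fixed at 1.00); the
prevalence table gives each region's posterior-mean prevalence with a
95% credible band; and 12 of 36 regions are flagged as significantly
high/low by the 95% credible-interval rule on the total spatial effect.

The `analysis/` directory stages the same workflow as numbered scripts
(simulate → descriptives/Moran → full fit → six-model DIC comparison),
writing tables under `results/`; set `STARLOGIT_SEED` to change the run
seed and `STARLOGIT_FULL=1` for the full 20,000-iteration schedule.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch — simulates a pooled
multi-survey dataset, applies listwise deletion, runs the Moran
clustering tests, fits the full interaction model and prints its DIC,
posterior odds ratios, predicted prevalence and spatial significance
classes — then writes the JSON report to `--out`.
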