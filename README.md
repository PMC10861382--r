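# twinace

One-step Bayesian twin modelling of ordinal questionnaire data with
genotype-environment interaction.

## The problem

Classical twin analyses of questionnaire phenotypes (ADHD symptom scales
and the like) first collapse item responses into a sum score, then
decompose its variance into additive-genetic (A), shared-environment (C)
and unique-environment (E) components. Sum scores carry heteroscedastic
measurement error — scales are least informative at the floor and ceiling —
and that error pattern can masquerade as genotype-environment interaction:
an apparent dependence of the environmental variance on the genetic value
that is really an artifact of the measurement. `twinace` implements the
one-step alternative: a generalized partial credit measurement model
(GPCM) for the raw, polytomous item scores is estimated *jointly* with the
biometric model, so measurement uncertainty propagates into the genetic
inference instead of biasing it.

The joint model, for individual $j$ in family $f$:

$$\theta_j = A_j + C_f + E_j,\qquad
  \sigma^2_{Ej} = \exp(\beta_0 + \beta_1 A_j),\qquad
  P(Y_{ij}=k\mid\theta_j) \propto \exp\Big(\sum_{h\le k}
  \alpha_i(\theta_j - b_{ih})\Big),$$

with MZ pairs sharing $A$ and DZ pairs correlating 0.5 (dominance
variants supported), and $\beta_1$ the AxE interaction: positive when
unique-environmental influences matter more for genetically predisposed
individuals. Headline quantities are the narrow-sense heritability
$h^2 = \sigma^2_A/(\sigma^2_A + \sigma^2_C + \exp\beta_0)$ and the
interaction effect size $\exp(\beta_1\sqrt{\sigma^2_A})$, the factor by
which the environmental variance grows over one genetic SD.

The package is aimed at behaviour-genetics researchers who want to run
this analysis — or study its statistical behaviour — without access to the
original cohort: it includes a synthetic twin-cohort generator, a
stand-alone psychometric stage (PCM/GPCM/GRM by marginal ML with AIC
comparison and information curves), a compiled Metropolis-within-Gibbs
sampler for the joint model with automatic imputation of missing item
scores, DIC model comparison, HPD intervals, Gelman-Rubin diagnostics, and
reporting utilities.

## Worked example

Simulate a cohort at realistic values (heritability 57%, strong positive
AxE), fit the joint AE+AxE model, and summarize:

```r
library(twinace)

params <- genetic_params("AE", sigma2_A = 0.25, beta0 = log(0.19), beta1 = 2.2)
sim <- simulate_twin_cohort(params, cohort_design(n_mz = 250, n_dz = 350),
                            seed = 11)

classical_stats(sim$data)$alpha
#> [1] 0.8818108            # Cronbach's alpha of the 9-item scale

fit <- run_chains(sim$data, model_spec("AE", interaction = TRUE),
                  n_chains = 2, burn_in = 5000, iterations = 5000, seed = 11)
summarize_fit(fit)
#>        parameter   mean     sd hpd_lower hpd_upper significant
#> 1       sigma2_A  0.205 0.0266     0.154     0.257          NA
#> 2          beta0 -1.784 0.1492    -2.092    -1.519        TRUE
#> 3          beta1  2.726 0.3034     2.191     3.348        TRUE
#> 4      exp_beta0  0.170 0.0248     0.121     0.216          NA
#> 5             h2  0.547 0.0572     0.439     0.660          NA
#> 6      h2_plugin  0.547     NA        NA        NA          NA
#> 7 total_variance  0.375     NA        NA        NA          NA
#> 8    effect_size  3.438     NA        NA        NA          NA
```

The posterior covers the generating values: `sigma2_A` 0.205 against a
truth of 0.25 and `beta1` 2.73 against 2.20, both with HPD intervals
containing the truth (single replicates at this reduced cohort size scatter
around the generating values; averaged over seeded replicates the posterior
means land at ~0.23 and ~2.23 — see the methods vignette), a clearly
positive interaction slope whose HPD excludes zero, and a plug-in
heritability of 55% against a generating 57%. The `credibility_curve(fit)`
table gives the posterior band of $\exp(\beta_0 + \beta_1 g)$ over the
estimated range of genetic values, and `model_selection_table()` compares
DIC across fits of the same data:

```r
fit0 <- run_chains(sim$data, model_spec("AE"), n_chains = 2,
                   burn_in = 5000, iterations = 5000, seed = 11)
model_selection_table(list(fit0, fit))
#>    model      DIC     Dbar       pD preferred
#> 1 AE+AxE 35345.72 34266.67 1079.047      TRUE
#> 2     AE 35429.02 34317.66 1111.368     FALSE
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/twinace.R` (verbs: `simulate`, `irt-fit`, `fit`, `compare`,
`report`, `pipeline`).

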