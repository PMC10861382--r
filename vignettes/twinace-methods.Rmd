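---
title: "Methods: one-step Bayesian twin modelling of ordinal item data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-step Bayesian twin modelling of ordinal item data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinace)
```

## The problem

Twin studies decompose phenotypic variance into additive genetic (A),
common-environmental (C), dominance (D) and unique-environmental (E)
components by exploiting the different genetic relatedness of monozygotic
(MZ) and dizygotic (DZ) twin pairs. When the phenotype is measured by a
handful of ordinal questionnaire items, working with sum scores confounds
trait variance with measurement error. Because the amount of information a
scale carries typically varies along the trait (floor and ceiling effects),
that confounding is *heteroscedastic* — and a naive test for
genotype-environment interaction, which asks precisely whether the
environmental variance changes with the genetic value, will then find
spurious interactions. The remedy implemented here is *one-step* estimation:
the item response model and the biometric model are fitted jointly, so the
measurement uncertainty in the latent trait propagates into the genetic
inference.

## Model

Each individual $j$ in family $f$ has a latent trait

$$\theta_j = A_j + C_f + D_j + E_j,$$

with zero-mean normal components: $A$ shared exactly within MZ pairs and
correlated $0.5$ within DZ pairs ($\mathrm{Var} = \sigma^2_A$); $C$ shared
within a family ($\sigma^2_C$, ACE only); $D$ shared within MZ pairs and
correlated $0.25$ within DZ pairs ($\sigma^2_D$, ADE only); and $E$
independent across individuals with

$$\sigma^2_{Ej} = \exp(\beta_0 + \beta_1 g_j),$$

where $g_j = A_j$ under AE/ACE (the AxE interaction) and
$g_j = A_j + D_j$ under ADE (GxE). The exponential keeps the variance
positive; $\beta_1 = 0$ recovers the homoscedastic model and the sign of
$\beta_1$ says whether unique-environmental influences matter more at high
or at low genetic values.

Responses to item $i$ with $K_i$ ordered categories follow the generalized
partial credit model (GPCM),

$$P(Y_{ij} = k \mid \theta_j) \propto
  \exp\!\Big(\sum_{h \le k} \alpha_i (\theta_j - b_{ih})\Big),$$

so the log-odds of category $k$ over $k - 1$ is
$\alpha_i(\theta_j - b_{ik})$. The first threshold $b_{i1}$ cancels from
the probabilities and is kept at 0 by convention.

Derived quantities: narrow-sense heritability
$h^2 = \sigma^2_A / (\sigma^2_A + \sigma^2_C + \exp\beta_0)$ (the
unique-environment component entering as its value at $g = 0$), total
phenotypic variance $\sigma^2_A + \sigma^2_C + \exp\beta_0$, and the
interaction effect size $\exp(\beta_1\sqrt{\sigma^2_A})$ — the factor by
which the unique-environmental variance grows over one genetic standard
deviation. Headline values use plug-in posterior means (the ratio of
posterior means, the transform at the posterior means); `summarize_fit()`
additionally reports the posterior mean of the per-draw $h^2$.

## Identification

Location is fixed by the zero means of all latent components and
$b_{i1} = 0$. Scale needs one more constraint: with free discriminations
and free variance components, multiplying $\theta$ by $c$ and dividing all
$\alpha_i$ by $c$ leaves the likelihood unchanged. Two conventions are
implemented:

* **`anchor = "geomean"` (default).** The sampler works in the expanded,
  scale-redundant space with all $I$ discriminations free, and every
  recorded draw is mapped to the identified scale on which the geometric
  mean of the discriminations is 1 (rescaling $\theta$, thresholds,
  variance components, $\beta_0$ and $\beta_1$ accordingly; the likelihood
  is invariant, so this is a deterministic functional of the draw). This
  parameter-expansion scheme spreads the scale information over all items.
* **`anchor = "alpha1"`.** The first item's discrimination is fixed at 1.

The geometric-mean convention is the default because anchoring on a single
item identifies the scale only through that one item's responses; in
simulation at moderate cohort sizes this produced a noticeable upward drift
of all variance components (the posterior can trade a common inflation of
$\theta$ against deflation of the eight unanchored discriminations at
little likelihood cost), whereas the geometric-mean constraint removed it.
The package's default synthetic item bank has both $\alpha_1 = 1$ and
geometric mean exactly 1, so generating truth and either fitted convention
live on the same scale.

## Priors

The defaults (`prior_spec()`) are proper and weakly informative:
half-normal(scale 2) on each component SD $\sigma_A, \sigma_C, \sigma_D$;
$N(0, 10^2)$ on $\beta_0$, $\beta_1$ and the free thresholds; and
lognormal(0, 1) on the discriminations. Variances are sampled on the log
scale with the appropriate change-of-variables terms. All hyperparameters
are configurable; none of the reported quantities is sensitive to doubling
or halving these scales in the simulations below, because the data carry
far more information than the priors at the cohort sizes used.

## Posterior computation

`run_chains()` runs a bespoke Metropolis-within-Gibbs sampler (compiled
via Rcpp). One iteration updates, in order:

1. **Missing item scores** — drawn from the GPCM predictive at the current
   $\theta_j$ (imputation, mirroring how a general-purpose Gibbs sampler
   treats missing observed nodes); imputed scores participate in the
   latent and item-parameter updates but never in the recorded deviance.
2. **$E_j$** — per-individual random-walk Metropolis (the GPCM row
   likelihood plus the heteroscedastic normal prior).
3. **$A$** — per MZ family (one shared value) and per DZ individual, the
   latter against the conditional prior
   $A_j \mid A_{\mathrm{co}} \sim N(A_{\mathrm{co}}/2,\ 0.75\,\sigma^2_A)$;
   the update includes the dependence of the $E$-prior on $A$ when
   $\beta_1 \ne 0$. **$D$** and **$C$** analogously where present.
4. **Item parameters** — random-walk Metropolis on $\log\alpha_i$ and each
   free threshold.
5. **Hyperparameters** — $\log\sigma^2$ components against their exact
   pair densities; $\beta_0, \beta_1$ against the heteroscedastic normal
   likelihood of the current $E$.

Proposal step sizes adapt toward a 44% acceptance rate during burn-in only
(frozen afterwards, preserving detailed balance for the retained draws).
All randomness flows through R's RNG, so a run is reproducible from
`set.seed()`; chain $c$ uses `seed + c - 1`.

The per-iteration cost is dominated by GPCM likelihood evaluations; these
factor the cumulative sums as
$\exp(s_k) = \exp(\alpha\theta)^k \exp(-\alpha\,\mathrm{cumsum}(b)_k)$
with per-item tables cached between parameter changes, so one person-item
evaluation needs a single `exp` and `log`, with a max-subtraction fallback
outside the tables' safe numeric range. The two code paths agree to
floating-point roundoff and the fallback is exercised in the unit tests.

**Deviance and DIC.** Every retained iteration records
$D = -2\sum \log P(y_{ij}\mid\theta_j)$ over originally observed cells,
conditional on the sampled latents and item parameters (the convention of
general-purpose Gibbs samplers). `dic()` uses $p_D = \bar D - D(\hat\psi)$
with $\hat\psi$ the posterior means of $\theta_j$ and the item parameters,
and $\mathrm{DIC} = \bar D + p_D$. Because the focus includes the
individual latents, $p_D$ is of the order of the number of individuals;
model comparison uses DIC *differences* between models fitted to the same
data, where that common bulk cancels.

**Convergence.** `gelman_rubin()` computes the potential scale reduction
factor from between/within-chain variances
($\hat V = \frac{n-1}{n}W + \frac{1}{n}B$, $\mathrm{PSRF} =
\sqrt{\hat V / W}$) for every hyperparameter; a fit is flagged
non-converged when any PSRF exceeds 1.1 — a flag, not an exception, since
non-stationarity is a legitimate finding (the ADE variants are expected to
show it on realistic data and are excluded from headline comparisons for
exactly that reason).

**Validation.** Sampler correctness is checked two independent ways: on a
homoscedastic AE subcase with the trait treated as directly observed, a
pure conjugate Gibbs sampler (`ae_theta_gibbs()`, inverse-gamma priors)
must match a dense 2-D grid posterior computed from the closed-form pair
likelihood; and the full joint density (`joint_log_density()`, an
independent R implementation, not the C++ code) must integrate over a
3-D latent grid to the same marginal data probability as a factorized
quadrature on tiny instances.

## The psychometric stage

`fit_irt()` implements the stand-alone measurement analysis: marginal
maximum likelihood for the PCM, GPCM and GRM with a standard-normal latent
density integrated by fixed Gauss-Hermite quadrature (61 nodes by default —
beyond ~40 nodes the log-likelihood changes are far below the EM stopping
tolerance). One twin per family is selected at random (seeded) to avoid
the within-family dependence; missing responses are simply skipped in the
likelihood (full-information ML); categories never observed are collapsed
into their neighbour, with a record in the result. The M-step maximizes
each item's expected complete-data log-likelihood by BFGS from the current
parameters, so the marginal log-likelihood is non-decreasing across EM
iterations; the GRM keeps its thresholds ordered through a log-increment
reparameterization. Models are compared by AIC ($-2\ell + 2p$); the latent
scale of this stage is the standard-normal convention, distinct from the
joint model's identification, so parameter values are not directly
comparable across the two stages.

## The synthetic-data generator

`generate_latents()` draws the biometric structure exactly as the model
assumes it: MZ pairs share one additive draw; DZ additive values are built
as $\sqrt{\sigma^2_A/2}\,(z_{\mathrm{family}} + z_{\mathrm{twin}})$,
giving the 0.5 correlation by construction (dominance analogously with
shared weight $1/4$); $E_j$ is drawn with variance
$\exp(\beta_0 + \beta_1 g_j)$. `generate_item_responses()` draws GPCM
categoricals at $\theta_j$, and `inject_missingness()` blanks item scores
completely at random following a per-family pattern; the default pattern
(95% of families complete, 2% missing one score, 1% missing five, 2%
missing a whole twin's scale) mirrors the missingness reported for a large
adolescent ADHD twin cohort. The default item bank
(`swan_item_bank()`) emulates a 9-item, 7-point symptom subscale:
discriminations 0.8–1.25 and category steps spread over roughly ±1.2 on
a latent scale whose typical SD is 0.6–0.8 under the default biometric
values; with those settings the generated data reproduce a Cronbach's
alpha near 0.89, matching the reliability reported for the real scale.

What the generator does *not* emulate: rater effects and sibling-contrast
effects, sex differences, non-normal latent components, and
informative missingness. Passing recovery tests therefore demonstrates
internal consistency of model and sampler under the model's own
assumptions — not robustness to these violations.

## Simulation scales and what they showed

Parameter recovery is assessed at a reduced cohort of 250 MZ + 350 DZ
pairs (the real cohort's MZ:DZ mix at roughly half size) with 2 chains of
5,000 burn-in + 5,000 retained iterations — sizes chosen so a full
replicate set runs on a laptop in minutes. At that scale individual
replicates scatter visibly around the generating values ($\beta_1$
posterior means ranged 1.6–2.9 over 15 seeded replicates in our runs,
with a modest upward skew of the replicate average, ≈ +0.1; $\sigma^2_A$
averaged ≈ 0.225 against a generating 0.25), reflecting the right-skewed
$\beta_1$ posterior — tail families carry most of the interaction
information — and its negative posterior correlation with $\sigma^2_A$.
Both effects shrink to nothing at double the cohort size (recovered means
≈ 2.19 and 0.26), and the $\beta_1$ skew also vanishes when the items are
made nearly noiseless — the expected behaviour of a correct one-step
estimator whose information is limited by the measurement scale, and the
reason recovery tolerances at the reduced scale are stated in units of the
reported posterior SDs.

Model selection (DIC preferring AE+AxE on interaction data and AE on
homoscedastic data) is checked at a smaller scale still (60 MZ + 90 DZ,
2 chains × 3,000 retained after 2,000 burn-in), where only the direction
of the DIC difference is meaningful, not its magnitude — deliberately
small, because the DIC penalty for an unused interaction parameter is
constant while the deviance's Monte Carlo noise grows with cohort size, so
small cohorts give the cleaner null-data comparison.

## Numerical choices and edge cases

* HPD intervals: exhaustive shortest-window search on the sorted draws
  (`hpd_interval()`); degenerate draws give a zero-width interval.
* Ties in DIC tables are all flagged preferred and ordered by model name.
* `credibility_curve()` uses equal-tailed bands by default (`type = "hpd"`
  per grid point available); at $g = 0$ the band is exactly the posterior
  band of $\exp(\beta_0)$. The default grid is the posterior means of the
  individual additive genetic values, i.e. the estimated range of genetic
  values in the sample.
* Zero-variance items make the item-rest correlation undefined; it is
  reported `NA` with a warning.
* Families in which both twins are missing every item score are excluded
  on CSV import, with a message; families must contribute exactly two
  twins.
* Degenerate variance components ($\sigma^2 = 0$) are valid for the
  generator but not for density evaluation or fitting, which require
  positive variances.

## Known limitations

* The ADE variants are implemented and sampled, but on realistic cohort
  sizes their chains often fail the PSRF check — dominance is barely
  identified from MZ/DZ data alone — so they are excluded from headline
  comparisons; the convergence flag propagates this honestly.
* DIC is the only model-comparison criterion implemented (no WAIC/LOO),
  and its latent-conditional focus makes absolute values large; only
  differences are interpretable.
* No sibling-contrast, rater-bias, sex-limitation or measured-moderator
  models.
* The psychometric stage is unidimensional; no DIF analysis.
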