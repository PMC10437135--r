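---
title: "Methods: leave-one-society-out unusualness and its explanatory models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leave-one-society-out unusualness and its explanatory models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The statistic

A song is a vector of categorical codings, one state per feature of a
declared scheme (for Cantometric data, 37 features such as vocal
organisation, interval width, nasality, tempo). Its **unusualness** within
its region is the log-likelihood of those states under regional state
frequencies estimated *without any song of the focal society*:

$$U(\text{song from } s \text{ in } r) \;=\; \sum_{f=1}^{F} \ln
\hat p_{r,-s}\!\left(x_f\right),$$

where $\hat p_{r,-s}(x)$ is the relative frequency of state $x$ among the
region's out-of-society songs. The leave-one-society-out (LOSO) design is
what makes the downstream style analysis meaningful: a society with many
recordings cannot make its own songs look typical, so similarity in
unusualness among a society's songs reflects a shared source, not
double-counting. Scores satisfy $U \le 0$, with $U = 0$ exactly when every
state the song uses is universal in its baseline; smaller values are more
unusual. Because every complete song contributes the same number of terms,
scores are comparable across songs.

Two conventions could be read into "summing state probabilities and taking
the log": the sum of logs (a log-likelihood) and the log of the summed
probabilities. The package computes the sum of logs. A log of a sum is not a
likelihood, its scale does not grow with the number of features, and it
cannot distinguish a song with one vanishingly rare state from a song with
several moderately common ones. The literal log-of-sum variant is retained
behind `convention = "log_of_sum"` for sensitivity analysis only.

**Zero counts.** A state never observed in the baseline would contribute
$\ln 0 = -\infty$. Such states receive a floor probability of
$1/(n+1)$, where $n$ is the number of baseline songs (`floor_rule`,
overridable with a fixed probability). The floor keeps scores finite, decays
as regional support grows, and never exceeds the order of the smallest
observable nonzero frequency $1/n$. Observed-state probabilities are *not*
renormalised after flooring; they remain plain relative frequencies, so the
statistic stays a genuine empirical log-likelihood wherever no flooring is
needed.

**Societal traits.** The same logic applies to categorical societal traits
(kinship and economic variables), where each society holds at most one state
per trait and the baseline is the region's other societies. Here the score
is the *mean* of $\ln \hat p$ over the society's non-missing traits rather
than the sum: trait coverage varies widely between societies, and a sum
would conflate being unusual with being well documented. `n_items_scored`
records how many traits entered each score. Societies alone in their region,
or with no usable traits in the requested theme, get a missing score rather
than a misleading one.

## Covariates of unusualness

- **Contact** — the number of other sampled societies within a great-circle
  radius (default 500 km; 250 and 1000 km available, and
  `select_radius()` chooses among them by LOO-ELPD on bivariate fits,
  reporting radii within 4 ELPD of the best as practically equivalent).
  Distances use the haversine formula on a sphere of radius 6371.0088 km
  (the IUGG mean); the boundary is inclusive. Counting is global by default
  — contact does not stop at region borders — with `within_region = TRUE`
  available.
- **Cultural isolation** — the patristic distance from the society's
  language tip to the nearest tip mapped to a different sampled society on a
  supplied phylogeny. Societies sharing a tip are at distance zero;
  societies without a tip mapping are dropped from this covariate rather
  than imputed.
- **Social organisation** — kinship and economic trait unusualness, as
  above.
- **Musical style** — for each song, the arithmetic mean unusualness of its
  society's *other* songs (`society_mean_loo`), missing for singleton
  societies. Like the statistic itself, it is leave-one-out by
  construction.

`assemble_predictors()` joins these per song, flags rows missing any
covariate, and (by default) standardizes response and covariates to mean 0,
sd 1 over the complete rows, using the sample (n−1) standard deviation.
Missing covariates are handled by listwise deletion with a reported count;
no imputation is attempted.

## The regression models

`ubm()` fits, via JAGS, a Gaussian regression with linear predictor over the
standardized covariates and an optional society random intercept:

- Model 1: `response ~ neighbours + phylo_nn + kinship_u + economic_u`
  with a society random intercept — the social-covariate model.
- Model 2: the same fixed effects plus `society_mean_loo`, without the
  random intercept — the random effect replaced by an observable style
  covariate.

Comparing the two partitions the explanation of unusualness: if Model 1's
fixed effects explain little (marginal R²) while its society intercept
explains much (conditional − marginal), and Model 2's `society_mean_loo`
recovers that gap as a fixed effect, then society identity — musical style —
is the dominant predictor. The aggregate kinship+economic trait score
(`general_u`) is computed on request but excluded from the default models,
since it is collinear with its two components.

Defaults follow common practice for standardized data: 4 chains, 4000
iterations with the first 2000 discarded as burn-in, Normal(0, 2.5) priors
on coefficients, half-Student-t(3, 0, 2.5) on standard deviations (all
overridable), 89% equal-tailed credible intervals (HPD by flag). Every fit
records its seed, chain count and draw counts; chain RNGs are derived
deterministically from the seed. Convergence is reported (split R-hat via
`coda`, effective sample sizes); a fit with any R-hat above 1.05 is flagged,
not discarded. A rank-deficient design matrix is a fatal error, and fewer
than ten rows per fixed effect triggers a warning.

**R² partition.** Per posterior draw, the variance of the fixed-effect
predictions over the fitted rows is set against the group variance
$\sigma_u^2$ and residual variance $\sigma^2$:
marginal $= \mathrm{var}(X\beta) / (\mathrm{var}(X\beta) + \sigma_u^2 +
\sigma^2)$, conditional adds $\sigma_u^2$ to the numerator; posterior means
are reported. Without a group term the two coincide by construction.

**Model comparison.** LOO-ELPD is estimated by Pareto-smoothed importance
sampling implemented in the package (generalized-Pareto tail fit with a weak
prior on the shape, tail-quantile smoothing, truncation at the raw maximum),
with the tail-shape diagnostic reported per observation. An exact
refit-one-per-row LOO (`exact_loo()`) serves as the small-instance oracle —
the test suite checks the two agree within the reported standard error — and
`kfold_cv()` provides standard k-fold cross-validation: k refits on a seeded
shuffle into k disjoint folds, held-out log predictive density per point,
and the across-fold stability of coefficient estimates. A held-out row whose
society was absent from the training rows has its random intercept
integrated out (predictive sd $\sqrt{\sigma^2+\sigma_u^2}$).

## The synthetic-data generator

`simulate_study()` produces the four inputs with the dependence structure
the analysis assumes, and records ground truth:

- **Repertoires.** Per region and feature, a baseline state distribution
  drawn from a symmetric Dirichlet (concentration `regional_concentration`,
  default 1). Each society's distribution is the mixture
  $(1-\lambda)\,\text{baseline} + \lambda\,\text{Dirichlet draw}$
  (`society_concentration`, default 0.5); songs are i.i.d. categorical. The
  style strength $\lambda$ (default 0.7) is the single dial connecting the
  generator to the analysis: at 0, societies are exchangeable within
  regions and the intraclass correlation of unusualness is ~0; as it grows,
  between-society variance comes to dominate and the within-society spread
  of unusualness shrinks. The Dirichlet mixture (rather than, say, a
  logit-normal) keeps expected frequencies in closed form for oracle tests.
- **Geography.** Societies scatter around a random regional centre with a
  Gaussian spread (default 300 km), converted to degrees with the local
  latitude cosine — adequate at cluster scales up to ~1000 km.
- **Language tree.** A pure-birth tree with one tip per society, rescaled
  to unit depth, tips assigned to societies at random.
- **Traits.** The song generator restated at the society level: one state
  per (society, trait), themed kinship/economic, missing completely at
  random (default 10%).

Default sizes — 6 regions × 15 societies, repertoire sizes uniform on 1–12,
37 six-state features — give ~90 societies and ~580 songs, a
tenth-scale corpus with the skewed repertoire sizes (minimum 1) that make
the LOSO and singleton edge cases exercise realistically. All randomness
derives from one master seed through fixed offsets (seed, +1, +2, +3 for
repertoires, geography, tree, traits), so components reproduce
independently. What the generator does *not* emulate: real Cantometric
feature semantics, correlated features, genre structure within repertoires,
real-world geography or language history. Tests passing on synthetic data
therefore validate the statistical machinery, not any empirical claim about
actual musical corpora.

`simulate_regression()` generates the regression problem directly
(standard-normal covariates, known coefficients, society intercepts, known
variance components) for recovery and calibration tests.

## Numerical conventions and degenerate inputs

- Score tables are sorted by (region, society, song id); all reductions are
  order-invariant, and the tests check permutation invariance explicitly.
- Top-percent selection takes the $\lceil pN \rceil$ smallest scores, ties
  broken by song id; a quantile-threshold mode is also provided, since a
  "top p%" read off a histogram tail can legitimately mean either.
- Modal profiles break ties toward the lower state code.
- A society alone in its region has no baseline: its songs are skipped and
  recorded, not scored against nothing. A region where every society is a
  singleton yields trait scores of `NA`. Standardizing a constant column is
  a fatal error rather than a silent division by zero.
- The default feature scheme shipped with the package is a *structural*
  default (37 features on the 13-point line, six tempo states); real
  analyses should read the release codebook via `read_scheme()`.

## Validation scale

The test suite validates exact properties on instances of up to 50 songs
(where brute-force recomputation is feasible to full floating precision) and
statistical recovery at reduced MCMC budgets chosen for tight Monte-Carlo
error at low cost: coefficient recovery at n = 500, interval calibration
over 200 null replicates at n = 60, variance-ratio recovery at n = 2000, and
the end-to-end style contrast on a default-scale study (~580 songs). The
acceptance script runs the full pipeline at the default study scale with
4-chain, 4000-iteration fits.

## Known limitations

- Regions are taken as given; the statistic inherits whatever arbitrariness
  the regional classification carries, and no sensitivity analysis over
  alternative regionalisations is built in.
- Frequencies treat features as independent; co-occurring rare states are
  each counted once, so a song with one systematically deviant *bundle* of
  features scores similarly to one with the same states scattered at
  random.
- The flooring rule for unseen states is a pragmatic choice; analyses in
  which many states are floored (tiny regions) should be read with care —
  `support_n` is recorded for exactly this reason.
- Gaussian likelihood only; no spatial or phylogenetic residual covariance.
- PSIS-LOO inherits the usual importance-sampling caveats; the Pareto-k
  diagnostic is reported and `exact_loo()` exists for verification on small
  data.
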