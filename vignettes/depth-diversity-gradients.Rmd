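---
title: "Methods: depth diversity gradients of submerged macrophytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth diversity gradients of submerged macrophytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakeddg)
```

## The problem

Submerged macrophytes are surveyed along transects running from the shoreline
to the lowest plant occurrence, divided into four depth classes (0–1, 1–2,
2–4, > 4 m). Species richness along this gradient — the depth diversity
gradient (DDG) — compresses one of the steepest environmental gradients in
nature (light, temperature, disturbance) into a few metres. `lakeddg`
characterises the DDG from such survey tables, asks what shapes it, and
whether it is shifting over years.

All depths are signed metres, negative downward. Each class is represented by
its midpoint: −0.5, −1.5, −3.0, and −5.0 m for the open-ended deepest class.
After ingestion every API works on midpoints, never labels.

## Data selection

Campaigns (one lake mapped in one year) enter the analysis population when
the lake is deep (maximum depth > 10 m), natural, dimictic, and has a natural
water-level dynamic; campaigns with a single transect are dropped (no
turnover can be measured); only submerged growth forms identified to species
rank are counted. The repeat-mapping rule — a lake must have at least two
distinct survey years — is evaluated on the campaigns that survive the other
rules, which makes `filter_records()` idempotent: a second pass removes
nothing. The alternative (counting years in the raw archive) can strand a
lake whose only repeat year was lost to the single-transect rule, so the
filter would not be a fixpoint.

Three nested tiers organise downstream analyses: all surviving campaigns
(*biodiversity*), those with complete environmental records
(*environment & biodiversity*), and lakes with at least three survey years
(*time series*).

## Richness partitioning

Per campaign and depth class, alpha richness is the mean over transects of
the per-transect species count, gamma richness the count over the union of
transects, and beta richness the additive complement gamma − alpha. Every
transect contributes a count — possibly zero — to all four depth classes:
the survey protocol spans the whole gradient, and without the zeros the mean
would be taken over a depth-dependent denominator. Beta is therefore never
negative and alpha + beta = gamma holds exactly in floating point (alpha is
a mean of integers over a fixed denominator).

## Peak measures and pattern types

The DDG curve of each component is summarised by the depth of its maximum
(D_max) and the maximum value (R_max). For alpha these are per-transect peaks
averaged across transects; for beta and gamma they are campaign-level argmaxes
of the profiles. Ties between depth classes are resolved by averaging the tied
midpoints, which is what places intermediate peak depths (e.g. −2.25 m)
between classes. Two conventions are ours to state:

* transects with no species anywhere have no defined argmax and are excluded
  from the averages (their count is reported);
* R_max for alpha is the mean of per-transect maxima, not the maximum of the
  mean profile — the two differ whenever transects peak at different depths,
  and a regression test pins the choice.

Pattern types partition the depth axis by D_max: decreasing (> −1 m), shallow
hump (−1 to −2 m), deep hump (−2 to −4 m), increasing (≤ −4 m). Boundary
values go to the deeper class; the choice is unobservable on pure midpoints
and only matters for tie-averaged peaks.

## Robust depth comparisons

Richness is compared across depth classes with all pairwise (Tukey) contrasts
of a cell-means linear model, using an HC3 sandwich covariance so that
non-normality, heteroscedasticity and unequal group sizes do not invalidate
the inference. Single-step adjusted p-values come from the joint distribution
of the maximum absolute t statistic, approximated by seeded Monte-Carlo
sampling of the multivariate normal with the contrasts' correlation matrix
(default 100,000 draws). The finite-sample multivariate-t refinement is
omitted; on exactly homoscedastic balanced fixtures the normal approximation
agrees with the classical studentized-range (Tukey HSD) probabilities within
0.002 at n = 400 per group, and the familywise error over 2,000 null datasets
(4 groups, n = 25) is 0.052 at nominal 0.05. With a single contrast the
adjusted p equals the unadjusted robust p; with several, the Monte-Carlo
estimate is floored at the unadjusted p so adjusted ≥ unadjusted holds under
simulation noise.

## Environmental drivers

Annual means of the twelve physiochemical variables use monthly surface
measurements, require at least eight monthly values, and set values below the
detection limit to zero. The stratification proxy Tempsd is the standard
deviation of temperature across the 0/−2/−4/−6 m series, computed per month
and then averaged over months with all four depths present — monthly-first
preserves the seasonal stratification signal that pooling across the year
would blur. Water-level fluctuation is WLF = MHW − MLW; from a raw gauge
series, MHW and MLW are means of annual extremes (the standard hydrological
definition).

Variables are log-transformed before ordination (natural log; columns
containing zeros are offset by half their smallest positive value; pH is
exempt, being already logarithmic). The PCA runs on the correlation matrix —
forced by incommensurable units — and retains the minimal prefix of axes
exceeding 80% cumulative variance. An axis is named by every variable whose
squared correlation with it exceeds 0.40, i.e. the axis carries more than 40%
of that variable's variance; axes are oriented so their dominant loading is
positive. Note a geometric fact that shapes tests: for two standardized
variables the sample correlation matrix has equal diagonal, so its
eigenvectors always lie at 45° and both variables name both axes; clean
one-variable axis names require genuine correlation structure (blocks of
collinear variables).

Peak measures are modelled with additive mixed models: one penalized-spline
smooth per retained PCA axis plus a lake-level random intercept, fitted by
REML through `mgcv`. Backward elimination removes the least significant
smooth and refits until everything remaining is significant at 0.05. Each
retained term's *drop contribution* is the decrease in deviance explained
when it is removed from the retained model, where deviance explained is
measured against the random-intercept-only baseline — this makes a single
retained term's drop contribution exactly its total explained deviance, and
keeps the reported quantity about the predictors rather than the lake
structure. A limitation worth stating: when several null candidates are
screened, the last survivor of backward elimination is the best-looking of
them, so the probability of a non-empty minimal model under a pure-noise
response is near P(min p < .05) over the candidates (≈ 14% for three), not
5%; `mgcv`'s approximate smooth p-values are additionally mildly
anti-conservative at this sample size. Stepwise minimal models should be read
as descriptive, not as error-controlled selection.

Whether the subset of campaigns with complete environmental data is
representative of the full population is checked by PERMANOVA (via
`vegan::adonis2`) on Euclidean distances of the standardized diversity
metrics, subset versus rest; a nonsignificant result supports treating the
subset as representative.

## Temporal change

Stability is quantified by the invariability coefficient IC = mean/sd, the
inverse coefficient of variation; constant series are flagged as infinitely
stable rather than erroring. Trends are ordinary least-squares slopes of each
measure on calendar year (numeric year, so uneven sampling is honoured), per
lake with at least three years and pooled over lakes. Significance classes
follow the conventional .001/.01/.05/.1 cut-points; trends are flagged at
p < .1 while pooled statements use .05 — both thresholds are reported rather
than reconciled. Because depths are signed negative, a positive D_max slope
means the richness peak is becoming shallower.

## The synthetic lake system

The generator builds virtual archives in the exact schemas the readers
consume, with known truth for validation. Species have Gaussian depth
niches: presence probability
`p(d) = max_presence · exp(−(d − optimum)² / (2 · tolerance²))`, scaled per
lake by an affinity multiplier, with independent Bernoulli draws per
transect, depth and species. The analytic expectation
E[alpha](d) = Σ p(d)·affinity and its argmax are returned as truth.

Defaults were chosen once to emulate a deep-lake monitoring population: 28
lakes, three transects per campaign, four survey years, a regional pool of
75 species. Two mechanisms produce the qualitative structure observed in such
programmes. Sparse lake affinity (each species absent from a given lake with
probability 0.6) keeps per-lake richness near 15 species and creates
between-lake turnover. Patchy shoreline specialists (half the pool, optima
near −0.6 m, reachable by a given transect with probability 0.25) concentrate
between-transect turnover — beta richness — in the shallow classes, as
shoreline habitat heterogeneity does in real lakes; without them beta simply
tracks gamma and peaks mid-depth. Under these defaults alpha is predominantly
deep-hump-shaped, beta predominantly decreasing, and the mean alpha peak is
about 4 species.

Monthly physiochemistry is annual lake mean + seasonal sinusoid + Gaussian
noise, with months dropped at a configurable rate and trace variables flagged
below detection so the eight-month and zero-substitution rules are exercised;
temperature is generated at four depths with depth-damped seasonal amplitude,
giving summer stratification and a seasonal Tempsd. Water-level statistics
are drawn around 0.58 ± 0.28 m of fluctuation. Multi-year runs can drift
niche optima (m/yr, positive = shallower) and grow or shrink the available
pool (species/yr), with the injected signs recorded as truth. Note that a
strong shallow-ward optimum drift also pushes niches out of the sampled
domain and lowers richness — the two drifts are not independent levers.

What the generator does not emulate: mechanistic light/temperature growth,
spatial autocorrelation among transects, disturbance regimes, observer error
in the Kohler scale. Passing tests therefore show the estimators recover the
structure this model encodes, not that real macrophyte data satisfy the
model.

## Problem sizes and numerical choices

The validation suite uses 1,000 random toy campaigns against a brute-force
set-enumeration oracle; 200 seeded replicates for peak recovery (one lake,
100 transects, 20 species with optima at −3 m); 2,000 null datasets for the
familywise-error study; 200 replicates each for stepwise selection and trend
recovery; 500 for the permuted-year null. Monte-Carlo draw counts are 4,000
per dataset inside the calibration loop and up to 500,000 for single-fixture
comparisons. Seeds are fixed in the tests; the pipeline derives per-stage
seeds deterministically from one master seed, and identical configurations
give identical outputs.
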