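---
title: "Methods: ecomorphology and invasion history in novel bird communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ecomorphology and invasion history in novel bird communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ecofitr)
```

## The scientific problem

Island bird communities dominated by introduced species are *novel*: their
members lack a shared evolutionary history, so it is an open question
whether the classical relationships between morphology and foraging
ecology (ecomorphology) persist, and whether a species' chance of
establishing after introduction depends on how distinct its ecological
niche is from the species already present (*ecological fitting*).

`ecofitr` implements this analysis as a reusable pipeline over four
tabular inputs — individual morphology records, timed foraging/movement
observations, diet and foraging-stratum niche profiles (EltonTraits-style
percentage distributions), and an island introduction history — plus a
synthetic-data generator that emulates all four tables with known ground
truth, so that every stage of the pipeline has a parameter-recovery or
oracle test without any external download.

## Morphological descriptors

From the five linear measurements (wing, tarsus, culmen, bill width and
depth at the nares; mm) and body mass (g) the package derives, per
individual:

* **tarsus-to-wing ratio** — long tarsi relative to wings indicate
  hopping, understory-adapted species; the reverse indicates
  flight-based foraging;
* **horizontal bill aspect** — culmen length / bill width;
* **bill slenderness** — culmen length / bill cross-sectional area at the
  nares (per mm); low values are robust bills, high values long thin
  bills.

The cross-sectional area is not uniquely defined by width and depth
alone. We approximate it as an ellipse, $\pi (w/2)(d/2)$, the natural
smooth-convex approximation of a bill section; a rectangular variant
($w \times d$) is selectable (`bill_area = "rectangle"`) because only the
relative ordering of species affects downstream model signs. Ratios are
computed per individual and then averaged per species at each site
(`compute_ratios()`), not taken as ratios of trait means; a regression
test pins this averaging order. Juvenile records are excluded everywhere.

Mass enters all models in kilograms. On 10–50 g passerines a kg-scale
predictor yields logit-scale coefficients in the hundreds, which is the
conventional reporting scale for such models.

## Morphospace and centroid distance

`pca_morphospace()` runs a PCA on the raw, centred (by default
unstandardised) measurements with the individual as the experimental
unit; all components are retained, so Euclidean distance between species
centroids in score space ($D_E$, `centroid_distances()`) equals the
distance on centred raw data (a rotation invariance the tests verify
numerically). Standardising first is available (`pca_standardize = TRUE`)
and changes $D_E$; the unstandardised default keeps the morphospace in
the original measurement units. Centroids are computed per species at
each site by default (within-site pairs only), with a pooled per-species
grouping for community-wide comparisons.

## Proportional similarity

Niche overlap between two resource-use distributions $p$ and $q$ over a
shared category set is the proportional similarity index

$$PS = \sum_i \min(p_i, q_i),$$

which is 1 for identical distributions, 0 for disjoint support, and
equals $1 - \tfrac12 \lVert p - q \rVert_1$ — an identity the test suite
uses as an independent oracle at $10^{-12}$ tolerance. Percent-scale
inputs (summing to 100, the EltonTraits convention) are divided by 100;
after conversion, sums must be within $10^{-6}$ of 1, a tolerance chosen
because published trait profiles are integers summing to exactly 100.

Behaviour-based PS uses relative frequency distributions over gleaning,
flycatching, nectarivory and frugivory (`behavior_distribution()`). An
observation event may carry several behaviour flags, so the frequency
denominator is a genuine choice: by default each *flag occurrence* counts
once (the distribution is then automatically proper); the alternative
splits each event's unit weight equally across its flags so no event
counts twice. Both are implemented; the default is documented rather than
asserted as the only defensible convention. Species–site groups never
observed foraging have no defined distribution and are excluded with a
warning — in sparse field data this realistically affects rarely foraging
insectivores, which is why the behaviour models take an
`exclude_species` argument.

## Incumbent communities and establishment features

`incumbent_community(records, year)` returns every native species plus
every species introduced *before or during* `year` that has not been
extirpated. Extirpation dates are last-report years, so a species last
reported in year $Y$ is treated as still present for introductions in
$Y$ (the `"inclusive"` boundary); the `"strict"` convention is available
and a regression test pins the default. Same-year introductions are
mutually incumbent.

`build_features()` assembles, per introduction: incumbent richness, the
number of distinct introduction years (a propagule-pressure proxy), and
the mean diet and stratum PS to the incumbent set. Species lacking
profiles never enter PS averages but do count toward richness by default
(`count_unprofiled_richness`), since presence, not data availability,
defines the community; this choice is a documented default, not an
assertion about any particular dataset. An empty incumbent set yields
`NA` features flagged for exclusion rather than silent dropping.

Two model variants are reported: all introduced species, and a variant
excluding game birds, whose persistence may reflect hunting-driven
stocking rather than ecology. Single-individual introductions are dropped
in both variants by default (`drop_single_individual`), switchable
because the narrower reading — applying the rule only to the no-game-bird
variant — is also defensible.

## The model suite

* **Behaviour models** (`fit_behavior_model()`): binomial GLMMs
  (Laplace-approximated ML, `lme4::glmer`) of each 0/1 behaviour,
  movement, or location response against site-averaged ratios, with
  random intercepts for site and species. Wald $z$ statistics are
  reported for every binomial mixed model.
* **Height models** (`fit_height_model()`): gaussian mixed models (REML)
  of canopy-relative maximum and minimum observation heights with the
  same random-effect structure; $t$ statistics with
  Satterthwaite-approximated (fractional, approximation-dependent)
  degrees of freedom via `lmerTest`. If the grouping is degenerate the
  fit degrades to OLS with a warning.
* **Similarity versus distance** (`fit_ps_vs_distance()`): quasibinomial
  GLM (logit link, moment dispersion) of pairwise PS on centroid distance
  $D_E$; $t$ statistics on $n_\mathrm{pairs} - 2$ residual df. Site was
  considered as a random effect for this model and found unnecessary; the
  model is deliberately a plain GLM.
* **Establishment model** (`fit_establishment_model()`): binomial GLMM of
  establishment on richness, introduction years, mean diet PS and mean
  stratum PS, with a taxonomic-family random intercept. Singleton
  families are retained. Because this model has exactly one scalar random
  effect, it is estimated by adaptive Gauss–Hermite quadrature (9 points)
  instead of the one-point Laplace special case: in our recovery
  experiments (300 introductions, diet-PS coefficient −8, family SD 0.5)
  quadrature lifted truth-in-95%-CI coverage from 88/100 to 96/100
  replicates, so the extra likelihood accuracy is not cosmetic. The
  crossed-random-effects behaviour models necessarily remain Laplace.

The registered behaviour models (`model_registry()`) encode the
literature-derived design: predictors per response, gaussian family for
the two height responses, and the prescribed number of focal species
(4 for foraging behaviours, 5 for movement/location/height responses).
Because the bill ratios are strongly correlated with one another, only
one bill descriptor enters each model. Predictors enter untransformed and
uncentred; lme4's "rescale variables" advisory triggered by mixing
richness (tens) with PS (unit scale) is recorded but not treated as
non-convergence, while genuine optimizer failures clear the `converged`
flag on the returned `ecofit_result`. No multiple-testing correction is
applied; $\alpha = 0.05$.

A numerical identity supports the random-effects implementation:
`glmm_zero_variance_limit()` pins every random-effect variance at zero in
the Laplace deviance and recovers plain-GLM estimates to $10^{-6}$,
verified in the acceptance tests.

## The synthetic-data generator

The generator (`sim_config()`, `simulate_community()`) defines the study
conditions under which the pipeline is validated:

* **Morphology** — per-species multivariate normal around five passerine
  archetypes (a small gleaning nectarivore through bulbul-sized
  frugivores), 5 species x 4 sites x 20 individuals by default.
  Non-positive draws are *resampled*, not truncated, so the distribution
  label stays honest. A zero covariance collapses individuals onto the
  species means exactly (a degenerate-noise oracle).
* **Observations** — 35 events per species x site (matching the
  order of magnitude of a season of hour-long point observations across
  four sites); each behaviour/movement flag is Bernoulli with logit
  intercept + slope x (site-averaged ratio), using the *same*
  `compute_ratios()` output the analysis later uses, so configured slopes
  are recoverable in the strict sense. Default slopes (e.g. +16 for
  gleaning on tarsus-to-wing, -29.4 for flycatching, -200 per kg for
  hanging) sit at the magnitudes reported for real novel-community
  ecomorphology so that recovery tests exercise realistic
  signal-to-noise. Relative heights are beta-distributed with support up
  to 1.3 x canopy (emergent trees), multiplied by per-point lognormal
  canopy heights (median 10 m).
* **Invasion history** — 126 introduced and 12 native species in 35
  families over 1850–2000; Dirichlet diet (10 categories, concentration
  0.5) and stratum (7 categories, 0.8) profiles scaled to percentages;
  first introduction years uniform over the span with a Poisson(0.7)
  number of extra years. The timeline is walked in arrival order and each
  establishment outcome is drawn from logit-scale coefficients
  (defaults at the magnitudes of published establishment models:
  richness -0.028, years +0.013, diet PS -6.649, stratum PS +1.131) plus
  a family random intercept (SD 0.5). The intercept default (2.6) was
  chosen once so that the mean linear predictor yields the observed
  marginal establishment frequency of roughly a third of introductions.
  Failed introductions receive a last-report year 1–30 years after
  introduction; the 1-year minimum keeps same-year incumbency
  well-defined, so the sequential draws and a post-hoc
  `build_features()` on the finished table agree exactly (a shared-code
  oracle the tests assert).
* **Flock sizes** are drawn from a configurable categorical distribution
  (singletons with probability 0.69, flocks of 2–10 with decreasing
  weights); nothing downstream is tested against it, since no empirical
  distribution is available to emulate.

What the generator does *not* emulate: spatial structure within sites,
temporal autocorrelation and weather-driven behaviour shifts, observer
error in height estimation, phylogenetic signal in traits or niche
profiles, and taxonomy-linked introduction effort. Passing
recovery tests therefore demonstrate correctness of the estimators under
the stated generative model, not robustness to every failure mode of
field data.

## Numerical choices and degenerate inputs

* PS normalisation tolerance $10^{-6}$ after percent conversion; ingest
  tolerates profile sums within 0.5 of 100 (integer rounding in published
  tables).
* Identical profiles return PS exactly 1 (guarded against summation
  round-off).
* Constant trait columns are dropped from the PCA with a warning;
  constant predictors are a refusal, not a silent singular fit.
* Sites with one species produce an empty distance table, not an error;
  empty exclusion results and empty event sets are errors.
* All fits are deterministic given data; the simulator derives one
  stream per operation from the single config seed, so a fixed seed
  fixes every emitted table byte-for-byte.

## Problem sizes used in the validation suite

The acceptance tests run 100-replicate recovery experiments for the
establishment model (300 introductions, diet-PS coefficient -8, family
SD 0.5) and the gleaning behaviour model (5 species x 4 sites x 250
events, tarsus-to-wing slope +16), plus a 500-replicate type-I
calibration at 60 events per species x site under a zero slope. These
sizes give Monte-Carlo error small enough to resolve the 90%-coverage
and 5% +/- 2% rejection criteria while keeping the whole suite
comfortably inside a routine check run.

## Known limitations

* The behaviour models treat site-averaged ratios as fixed covariates;
  measurement uncertainty in the site means is not propagated.
* Satterthwaite df are approximation-dependent; other mixed-model
  implementations will print slightly different fractional df.
* The quasibinomial PS model treats pairwise overlaps as independent
  observations; pair non-independence (each species appears in several
  pairs) is inherited from the original design and not corrected here.
* The establishment model conditions on recorded introduction histories;
  detection failure for briefly persisting species is not modelled.
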