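# ecofitr

Ecomorphology and invasion-history analysis of novel (introduction-dominated)
bird communities.

## What problem this package addresses

On heavily invaded islands, forest bird communities are *novel*: most
species never co-evolved. Two linked questions follow, and this package
implements the full analysis pipeline for both:

1. **Does form still predict function?** Relate foraging behaviour
   (gleaning, flycatching, nectarivory, frugivory; movement modes;
   foraging height and in-plant location) to morphology via bespoke
   ratios — tarsus-to-wing, horizontal bill aspect (culmen/width), and
   bill slenderness (culmen / bill cross-sectional area at the nares) —
   using binomial and gaussian mixed models with site and species random
   intercepts, and relate pairwise niche similarity to pairwise
   morphospace distance.
2. **Did ecological fitting shape assembly?** Reconstruct the incumbent
   community at each historical introduction date and model establishment
   success as a function of niche distinctiveness.

The central statistic is the proportional similarity index between two
resource-use distributions *p* and *q* over shared categories:

```
PS = Σ_i min(p_i, q_i)        (= 1 − ‖p − q‖₁ / 2)
```

PS = 1 means identical niches, PS → 0 disjoint niches. Establishment is
modelled as

```
logit P(establish) = β₀ + β₁·richness + β₂·years_introduced
                   + β₃·PS_diet + β₄·PS_for + u_family
```

where `PS_diet` and `PS_for` are the mean similarities of the newcomer's
diet and foraging-stratum profiles to every incumbent at its introduction
date, and `u_family` is a taxonomic-family random intercept.

A first-class synthetic-data module generates all four input tables
(morphology, observations, niche profiles, introduction history) with
known ground truth, so every stage has parameter-recovery and oracle
tests with no external data. The package is equally usable on real data
via the `read_*()` ingest functions.

## Worked example

```r
library(ecofitr)

cfg <- sim_config(seed = 7)          # study-scale defaults
sim <- simulate_community(cfg)

ratios <- compute_ratios(sim$morphology)
head(ratios, 3)
#>   species site  tarsus_to_wing horizontal_bill_aspect bill_slenderness mass_mean
#> 1 sp01    site1          0.296                   2.76             1.03      10.9
#> 2 sp01    site2          0.298                   2.89             1.10      11.3
#> 3 sp01    site3          0.297                   2.82             1.06      11.6
```

Fit the gleaning model (binomial GLMM, site + species random intercepts):

```r
fit_behavior_model(response_vectors(sim$observations), ratios,
                   "gleaning", c("bill_slenderness", "tarsus_to_wing"))
#> Model fit (binomial), n = 700; groups: species=5, site=4
#> ** singular random-effect fit (variance at 0) **
#>              term estimate     se statistic df   p_value
#>       (Intercept)  -5.5952 0.5639   -9.9216 NA 3.353e-23
#>  bill_slenderness   0.3001 0.5503    0.5453 NA 5.855e-01
#>    tarsus_to_wing  17.2687 1.8276    9.4489 NA 3.423e-21
```

The generator's true gleaning slope on tarsus-to-wing is +16 on the logit
scale; the fit recovers 17.3 ± 1.8. The singular-fit note is expected
here: the generator placed no extra species/site variance beyond the
ratio effect, and the model correctly estimates those variances at zero.

Reconstruct the invasion history and fit the establishment model:

```r
pp <- pairwise_ps(sim$profiles)
features <- build_features(sim$introductions,
                           pp[pp$kind == "diet", ],
                           pp[pp$kind == "foraging_stratum", ])
fit_establishment_model(features, mode = "no_gamebirds")
#> Model fit (binomial), n = 100; groups: family=30
#>                  term estimate      se statistic df p_value
#>           (Intercept)  1.25564 3.71002   0.33845 NA  0.7350
#>    incumbent_richness -0.05378 0.02502  -2.14942 NA  0.0316
#>  n_introduction_years -0.52056 0.46128  -1.12852 NA  0.2591
#>          mean_ps_diet  1.11727 5.75854   0.19402 NA  0.8462
#>           mean_ps_for  0.02237 5.48283   0.00408 NA  0.9967
#> mode: no_gamebirds
```

With only ~100 usable introductions a single simulated history is a noisy
draw (note the PS standard errors near 6): here the richness effect is
resolved but the diet-PS coefficient is not. The test suite demonstrates
systematic recovery of the diet-PS effect across 100 replicate histories;
single-history coefficient tables should be read with their standard
errors, exactly as in real invasion records of this size.

`run_pipeline(run_config(sim = sim_config(seed = 1)), out_dir = "out")`
runs everything — ratios, PCA morphospace and centroid distances,
behaviour distributions, all pairwise PS tables, the feature table, and
the complete registered model suite — and writes the derived tables,
coefficient table, and a provenance record; identical seeds yield
byte-identical output directories.

See `vignettes/ecofitr-methods.Rmd` for the model assumptions, the
conventions the pipeline pins (ratio averaging order, behaviour-frequency
denominator, extirpation boundary, PCA scaling), and what the synthetic
generator does and does not emulate.

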