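# mesorefugia

Do mesophotic reefs shelter the fish assemblages of the shallow reefs above
them? The *deep reef refugia hypothesis* holds that disturbance declines
with depth, so deeper reefs — the mesophotic zone, receiving 10% to 0.1% of
surface light — may buffer shallow communities against warming, bleaching
and storms. `mesorefugia` implements a complete, testable pipeline for
grading that refuge potential from video-transect fish surveys, satellite
water-turbidity series and species trait/taxonomy tables, aimed at reef
ecologists and MPA monitoring programmes.

## What it computes

**Mesophotic zone delimitation.** Monthly Kd490 (diffuse attenuation at
490 nm, m⁻¹) is converted to the PAR-band coefficient with the Morel Case-I
relation

    KdPAR = 0.0864 + 0.884·Kd490 − 0.00137 / Kd490   (valid Kd490 < 0.2 m⁻¹)

and the seasonal band follows from the optical depths at 10%, 1% and 0.1%
surface light, using the seasonal minimum (Kd1) and maximum (Kd2) monthly
mean KdPAR:

    z10% = 2.3 / Kd2,   z1% = 4.6 / ((Kd1+Kd2)/2),   z0.1% = 6.9 / Kd1

(2.3, 4.6, 6.9 are −ln 0.10, −ln 0.01, −ln 0.001). Transects at or above
the upper limit are "shallow", deeper ones "mesophotic".

**Diversity of transect assemblages.** From a transect × species count
matrix the package computes taxonomic Hill numbers (richness q = 0,
Shannon-exponential q = 1), attribute-diversity functional Hill numbers
over functional entities (FEs: unique combinations of six categorical
traits — size class, mobility, activity period, gregariousness, water-column
position, diet) with τ-truncated Gower distances, abundance-weighted
taxonomic distinctness Δ\* with a permutation funnel, and the convex-hull
indices in a 4-axis PCoA trait space:

* **FRic** — assemblage hull volume ÷ pool hull volume (own exact
  d-dimensional hull engine);
* **FOri** — abundance-weighted nearest-neighbour isolation of FEs, scaled
  by the pool maximum (inverse proxy of redundancy);
* **FDiv** — abundance-weighted divergence of FEs from the centroid of the
  assemblage hull vertices.

**Inference.** Composition differences across zone × year × season × site
are tested with a multivariate negative-binomial GLM: per-species NB
regressions (own IRLS + ML dispersion core, in C++), sequential
sum-of-likelihood-ratio deviances, and p-values from the PIT-trap
bootstrap, which resamples probability-integral-transform residuals by
whole transects to preserve cross-species correlation. Each diversity
index is modelled as `index ~ zone + (1|year) + (1|season) + (1|site)`
with Poisson (richness) or Gamma log-link (other indices) GLMMs.

**Classification.** The evidence pattern — taxonomic similarity, functional
similarity, zone-exclusive species and FEs, functional-volume overlap — is
mapped to one of five categories: `not_refugia`, `partial_refugia`,
`functional_refugia`, `full_refugia`, `enriched_refugia`, with a full rule
trace.

A synthetic-data module generates species pools (trait tables, nested
six-rank taxonomies, zone affinities), negative-binomial factorial surveys
with structural zeros for zone-exclusive species, benthic point-intercept
records and seasonal Kd490 series, so the entire pipeline runs and is
tested without any field data.

## Worked example

```r
library(mesorefugia)

kd <- generate_kd490_series(turbidity_config(seed = 42))
seasonal_zone_limits(kd)
#>   season    kd1   kd2  z10   z1  z01
#> 1   cold 0.1493 0.176 13.0 28.2 46.2
#> 2   warm 0.0783 0.104 22.1 50.5 88.1

res <- run_pipeline(seed = 42, n_boot = 99)
res$venn
#> Species Venn partition by stratum
#>   shared: 52 (54%)  shallow-only: 29  mesophotic-only: 15
#>   totals: shallow 81, mesophotic 67, overall 96

res$mv_test
#>     term res_df deviance p_value
#> 1   zone    182   5922.2    0.01
#> 2   year    181    105.1    0.38
#> 3 season    180    173.9    0.01
#> 4   site    178    381.1    0.01

res$classification
#> Refuge potential: partial_refugia
#> rule trace (first TRUE fires):
#>   not_refugia        : false
#>   enriched_refugia   : false
#>   full_refugia       : false
#>   partial_refugia    : TRUE
#>   functional_refugia : false
```

Reading the output: the cold season is more turbid (higher KdPAR), so its
mesophotic band (13–46 m here) is shallower and narrower than the warm
season's (22–88 m); the upper limit used operationally is the seasonal
minimum z10%. The synthetic survey reproduces a pool of 96 species with 52
shared between strata; composition differs by zone (PIT-trap p = 0.01 at 99
resamples), the mesophotic zone is the less diverse stratum, and both
strata hold exclusive species and trait combinations — the partial-refugia
pattern.

## Vignette

`vignettes/refuge-evaluation.Rmd` documents the models, their assumptions,
the synthetic-data generator's design and its limits, numerical choices
(hull degeneracy, τ selection, PCoA eigenvalue handling) and the open
design decisions.
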