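---
title: "Evaluating mesophotic reefs as refuges for shallow reef-fish assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating mesophotic reefs as refuges for shallow reef-fish assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesorefugia)
```

## The question and the evidence model

The deep reef refugia hypothesis proposes that disturbance attenuates with
depth, so mesophotic reefs (the band receiving 10% to 0.1% of surface
photosynthetically active radiation) may buffer shallow reef communities.
Whether they do is not a single yes/no test: a deep zone can hold the same
species, only the same *functions*, or neither. `mesorefugia` therefore
assembles three complementary descriptions of each video-transect fish
assemblage — taxonomic (Hill numbers), functional (entity-based convex-hull
indices and functional Hill numbers) and phylogenetic-proxy (taxonomic
distinctness on the Linnaean tree) — tests each for differences between
depth strata, and maps the resulting evidence pattern to one of five
ordered categories from `not_refugia` to `enriched_refugia`.

## Delimiting the mesophotic zone

Satellite Kd490 (m^-1^, monthly) is converted to the PAR-band attenuation
coefficient with the Morel Case-I relation

$$K_{dPAR} = 0.0864 + 0.884\,K_{d490} - 0.00137/K_{d490},$$

valid for clear phytoplankton-dominated water (Kd490 < 0.2 m^-1^; the
function warns outside this range). Two notational points deserve care,
because garbled renderings of this equation circulate. First, the linear
coefficient is 0.884; the variant 0.0884 sometimes seen in secondary
sources maps Kd490 = 0.09 to about 0.08 m^-1^ instead of 0.15 m^-1^ and is
inconsistent with the Case-I literature — it is available behind
`printed_eq1 = TRUE` purely for audit. Second, the final term divides by
Kd490 (it is the $K_{d490}^{-1}$ term of the original regression).

Optical depths then follow from Beer–Lambert attenuation. With $K_{d1}$ and
$K_{d2}$ the minimum and maximum monthly mean $K_{dPAR}$ within a season,

$$z_{10\%} = \frac{2.3}{K_{d2}}, \qquad
  z_{1\%} = \frac{4.6}{(K_{d1}+K_{d2})/2}, \qquad
  z_{0.1\%} = \frac{6.9}{K_{d1}},$$

where 2.3, 4.6 and 6.9 are $-\ln 0.10$, $-\ln 0.01$ and $-\ln 0.001$. The
three depths are the upper limit, midpoint and lower limit of the
mesophotic band; pairing the *maximum* attenuation with the upper limit and
the *minimum* with the lower limit makes the band conservative at both
ends. The ordering $z_{10\%} < z_{1\%} < z_{0.1\%}$ holds for every valid
input because $2.3 < 4.6 < 6.9$ while the denominators decrease.

Transects are assigned to strata against a single operational upper limit
(default 21 m, the seasonal minimum $z_{10\%}$ under the most transparent
conditions in the motivating region — "the mesophotic zone under optimal
conditions"). The boundary is closed on the shallow side: a transect at
exactly the limit is shallow. Monthly means are pooled across sites by
default; `by_site = TRUE` takes the min/max over site-months instead, for
regions with strong cross-site turbidity gradients.

## The synthetic survey generator

Every downstream stage is exercised on synthetic data whose defaults are
the structure of a two-year ROV monitoring campaign in a subtropical MPA:

* a pool of 96 species partitioned by largest-remainder rounding of the
  fractions (0.54, 0.30, 0.16) into 52 shared, 29 shallow-exclusive and 15
  mesophotic-exclusive species;
* 3 sites × 2 strata × 2 seasons × 2 years, with per-year transect totals
  of 94 and 95 (189 five-minute transects in all) allocated to cells by
  largest remainder — the published totals are per-year only, so a
  near-balanced allocation is assumed;
* negative-binomial counts, Var$(y) = \mu + \mu^2/\theta$ with θ = 1, and a
  log-linear mean over the design factors (default zone effect +0.7 on the
  log scale, i.e. richer shallow assemblages);
* a per-species lognormal baseline spread (SD = 1 on the log scale) giving
  the long-tailed rank-abundance structure real surveys show — without it
  every species is equally common and per-transect richness is unrealistic;
* *structural zeros*: a shallow-exclusive species has expected abundance
  exactly 0 in every mesophotic transect and vice versa. Exclusivity is
  thus a property of the generating process, not a sampling accident, so
  the Venn partition of a sufficiently sampled survey recovers the pool
  partition exactly — a sharp, testable property;
* seasonal Kd490 with the cold season more turbid (defaults 0.08–0.12
  m^-1^ cold vs 0.035–0.055 m^-1^ warm, Gaussian noise SD 0.004 m^-1^,
  floored at a small positive value), matching wind-driven winter mixing;
* 30-point benthic point-intercept records per transect over
  sand/gravel/block/rock plus soft/black coral counts and hard-coral cover.

Each generator derives its RNG stream from the config seed and a fixed
purpose tag (`seed' = (1009·seed + 101·purpose) mod 2^31−1`), so generators
are bit-reproducible independently of call order.

What the generator does **not** emulate: detection error and its depth
dependence, species-level trait–abundance correlations, temporal
autocorrelation within dives, spatial structure within sites, and
taxonomy–trait covariance (traits are drawn independently of the lineage).
Passing tests on synthetic data therefore demonstrate the *algorithms* are
correct under the stated model, not that the model captures every feature
of field data.

## Functional space and indices

Species sharing all six trait categories (size class, mobility, activity,
gregariousness, position, diet) collapse into one functional entity (FE),
coded by concatenating category indices. Distances between FEs use the
classic Gower coefficient: nominal traits contribute 0/1, ordinal traits
the absolute rank difference divided by the scheme range (levels − 1), all
six traits equally weighted. The scheme range (not the observed range) is
used so distances do not change when a rare extreme category drops out of
a subset; `cluster::daisy` reproduces the same numbers when both extremes
are observed, which the tests exploit as a cross-check.

Principal coordinates are obtained by eigendecomposition of the
double-centred $-D^2/2$ matrix. Gower distances on categories are generally
non-Euclidean, so some eigenvalues are negative; they are reported but
dropped from the coordinates, and explained variance is computed over the
positive part only. No Cailliez/Lingoes correction is applied — the common
default in trait-space practice; the eigenvalue vector is returned so users
can judge the distortion. Four axes are kept by default, the usual
compromise at which explained variance begins to plateau; the selection
helper reports the explained variance at *m* and *m*+1 axes.

FRic is the assemblage hull volume over the pool hull volume, computed by
an exact incremental (beneath-beyond) convex-hull algorithm written for
small point clouds in up to ~6 dimensions; its volumes are validated
against closed forms (simplices, hypercubes) and a facet-enumeration +
Monte-Carlo rejection oracle. Assemblages with fewer than axes + 1 affinely
independent FEs have no 4-volume; they yield a *flagged missing value*, not
a zero — a silent 0 would bias zone comparisons towards finding shallow
zones richer. The S ≥ 6 richness filter (species ≥ number of traits) is
necessary but not sufficient for non-degeneracy, hence the flag. FOri and
FDiv follow their originals: FOri is the abundance-weighted mean
nearest-neighbour distance of the assemblage's FEs within the *global
pool*, scaled by the pool maximum; FDiv measures whether abundant FEs sit
far from the centroid of the assemblage's hull vertices. All three are
computed on FE points weighted by summed relative FE abundance, not on
species points: the trait space has one point per unique trait
combination, so duplicating it per species would double-weight redundant
species in the hull geometry.

## Hill numbers, Δ\* and the funnel

Taxonomic Hill numbers: $^0D = S$, $^1D = \exp(-\sum p_i \ln p_i)$, general
$q$ as $(\sum p_i^q)^{1/(1-q)}$. Functional Hill numbers use the
attribute-diversity framework with distances truncated at a threshold τ:
$a_i = \sum_j (1 - \min(d_{ij},\tau)/\tau)\,p_j$, $v_i = p_i/a_i$, and the
order-q sum over $v_i a_i^q$. τ defaults to the mean nonzero pairwise FE
distance in the pool ("max" is available); since the index value depends on
τ, the value used is stored on the profile object. At τ below every
pairwise distance the functional Hill number equals the taxonomic one; at
zero distances it is 1.

Taxonomic distinctness Δ\* is the abundance-weighted mean Linnaean path
length between individuals of different species, with path length ω equal
to the level index of the lowest shared rank (1 = same genus, …, 6 =
sharing at most the superclass) and the scale fixed so the maximum possible
path is 100. Note one convention choice: a pair sharing *only* the
superclass already scores the maximum (100), and a hypothetical pair
sharing nothing is capped at the same value; `vegan::taxa2dist` instead
reserves the maximum for pairs differing at every level, so its values
differ by a factor of 5/6 for top-level pairs — the closed-form unit tests
pin this package's convention. The 95% funnel draws `n_draws` random
subsets per subsample size *m* from the master list with *equal*
abundances and returns the mean and 2.5/97.5 percentiles. The equal-weight
null reflects that the master list carries no abundance structure;
percentile bounds are used rather than a normal approximation because the
Δ\* null distribution is left-skewed at small *m*.

## Inference

**Composition.** Counts are fourth-root transformed (down-weighting
dominant species) before Bray–Curtis dissimilarity; ordination uses nMDS
(`vegan::monoMDS` via `metaMDS`, random restarts, stress-1), with
environmental vectors fitted by `vegan::envfit`. All-zero transects are
always dropped (their dissimilarity is undefined); an optional robust-SD
outlier flag is off by default and only ever *flags* points.

**Multivariate NB GLM.** The deviance test fits one NB regression per
species (log link; IRLS with θ by maximum-likelihood profiling — the
compiled core reproduces `MASS::glm.nb` to machine precision and exploits
the integer responses to evaluate all Γ-function terms as elementary
sums). Terms enter sequentially (Type-I) in the order given — main effects
first, interactions after, matching the monitoring design's reporting
convention; marginal testing can be emulated by reordering the formula.
The statistic per term is the sum across species of likelihood-ratio
statistics between nested fits. P-values come from the PIT-trap bootstrap:
probability-integral-transform residuals are computed under the smaller
model, *whole transect rows* are resampled with replacement — preserving
the cross-species correlation that motivates a multivariate test —
pseudo-counts are rebuilt through the null inverse CDFs, and the statistic
is recomputed; `p = (1 + \#\{boot ≥ obs\})/(n_{boot}+1)`, never exactly
zero. Species that are all-zero (in the data or a resample) are excluded
from the sum for that fit, and degenerate fits are flagged rather than
propagated. Under a permuted-label global null with realistic shared
transect effects the test holds its size; with fully independent species it
is mildly conservative, because joint row resampling couples the
species-level statistics through the shared resampling weights while the
observed statistics are uncoupled.

**GLMMs.** Each index is modelled as
`index ~ zone + (1|year) + (1|season) + (1|site)` by Laplace ML
(`lme4::glmer`), Poisson log for integer richness and Gamma *log* for the
positive indices — the canonical inverse link is numerically fragile for
strictly positive responses near zero and makes the zone contrast
non-interpretable as a ratio. Random-effect variances estimated at zero are
reported as boundary fits (the model then collapses to a GLM, which the
tests verify as an oracle equivalence). Zone effects are judged at
p < 0.05 (Wald); the borderline case p = 0.05 counts as *not* significant
under the strict inequality, and that rule is what the evidence assembly
uses.

## The five-category classifier

The classifier is a total, deterministic rule cascade over the evidence:

1. `not_refugia` — taxonomically and functionally dissimilar with no
   functional-volume overlap;
2. `enriched_refugia` — both similar and the deep zone holds exclusives;
3. `full_refugia` — both similar;
4. `partial_refugia` — deep diversity ≤ shallow and both zones hold
   exclusive species *and* exclusive FEs;
5. `functional_refugia` — only functional diversity similar.

The genuinely open design point is the boundary between rules 4 and 5 when
functional diversity is similar *and* both zones hold exclusives. The
default evaluates partial first: maintained functions with two-sided
exclusivity means the deep zone shelters only the shared fraction of the
assemblage, which is the partial pattern; `partial_before_functional =
FALSE` flips the precedence for users who read functional similarity as
the stronger signal. Functional similarity aggregates the functional Hill
numbers, FOri and FDiv; FRic is reported but excluded from the vote by
default because hull volume tracks richness so strongly that it would veto
functional similarity whenever richness differs, even when redundancy and
divergence are maintained. Volume overlap is operationalised as the hull
volume of FEs present in both strata over the pool hull volume (0 when the
shared set is degenerate).

## Numerical choices and problem sizes

Hull computations scale the degeneracy tolerance by the coordinate range;
facet construction skips numerically degenerate slivers. The NB core clamps
θ to [10^-3^, 10^7^] (the upper bound is the Poisson limit) and linear
predictors to ±30. The test suite sizes its simulations to run on one CPU
in minutes while keeping Monte-Carlo error well inside the asserted
tolerances: 500 replicates at 199 bootstrap resamples for the type-I-error
study of the multivariate test (20 species × 60 transects), 500 replicates
for the Gamma-GLMM size study (n = 200), 3·10^5^ rejection samples per
hull-volume comparison at a 2% tolerance, and 1000 random assemblages for
the Hill-number identities. The pipeline default of `n_boot = 99` is a
smoke-test setting; use 999 for reportable p-values.

## Limitations

Trait categories are fixed and complete by assumption (no imputation); the
distinctness tree is the Linnaean hierarchy, not a molecular phylogeny; the
hull engine targets tens of FEs in ≤ 6 dimensions, not thousands of points;
PERMANOVA-style distance-based tests and model selection are intentionally
out of scope; and the classifier grades evidence patterns — it does not
model connectivity or larval dispersal, which a full refugia argument would
also need.
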