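---
title: "Estimating community resistance potential from tolerance breadth and response asynchrony"
author: "commresist authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating community resistance potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commresist)
```

## The problem

Whether a species-rich microbial community is also a disturbance-tolerant
one depends on *which* species it holds: how widely each member tolerates
environmental variation, and how differently the members respond when the
environment shifts. `commresist` turns a cross-sectional survey — an OTU
count table over many samples plus the environmental conditions of each
sample — into two community-level indexes that capture exactly those two
ingredients, and combines them into a single resistance potential.

The package treats space as a substitute for time: an OTU observed to
thrive across chemically and climatically disparate sites is taken to
tolerate such variation, and two OTUs whose abundances move in opposite
directions along the gradient are taken to respond asynchronously to a
change. Both readings are inferences from occupancy patterns, not
physiological measurements; this is the central assumption of the whole
approach, and it is why the package ships a generative simulator in which
the assumption holds by construction and recovery can be verified.

## Per-OTU tolerance breadth

Environmental variables are first z-scored (`standardize_env()`, sample-sd
convention, computed over **all** samples of the survey, so that breadths
of different OTUs are measured in one common space). For OTU $m$ with read
counts $a_j$ in the samples $j$ it occupies, and standardized environment
vectors $x_j$, the abundance-weighted centroid is

$$C = \frac{\sum_j a_j x_j}{\sum_j a_j},$$

and the tolerance breadth is the abundance-weighted mean distance to it,

$$\mathrm{TB}_m = \frac{\sum_j a_j z_j}{\sum_j a_j},
  \qquad z_j = \lVert x_j - C \rVert.$$

This is an abundance-weighted multivariate dispersion. Distances are
Euclidean on the z-scored variables: the dispersion construction works for
any dissimilarity via a principal-coordinates embedding, but for Euclidean
input the direct computation above is exactly equivalent to that route (no
negative eigenvalues arise), so the package implements the direct form
only. TB is invariant to rescaling an OTU's counts (weights are ratios), it
is 0 for an OTU occupying a single sample (flagged via `n_occupied` so
users can filter), and it has no upper bound.

Putative **generalists** and **specialists** are the upper and lower tails
of the TB distribution (`classify_ecotypes()`). Quantiles use the
linear-interpolation (type-7) convention, with $\geq$ for the generalist
threshold and $\leq$ for the specialist one; an OTU qualifying for both
(possible only for degenerate TB distributions) is labelled `neither` and
reported. The quantile convention is a declared choice — any fixed
convention shifts thresholds by at most one order statistic.

## Response asynchrony and the community indexes

Pairwise response asynchrony is $\mathrm{RA}_{ij} = -\rho_{ij}$, the
negated Spearman correlation of the two OTUs' relative abundances across
**all** samples (zeros included, average ranks for ties). Computing RA once
on the full table and then restricting to each sample's members keeps one
OTU pair's asynchrony a global property of the gradient rather than a
per-sample quantity. OTUs with constant profiles have undefined rank
correlations; their entries are `NA` and they are excluded from the
numerator and denominator of every community mean that touches them. The
diagonal is $-1$: an OTU is perfectly synchronous with itself, which is
also why self-pairs are excluded from the community mean below.

For one sample with within-sample relative abundances $a_i$:

$$\mathrm{CMTB} = \frac{\sum_m a_m \mathrm{TB}_m}{\sum_m a_m}, \qquad
  \mathrm{CMRA} = \frac{\sum_{i<j} a_i a_j \mathrm{RA}_{ij}}
                       {\sum_{i<j} a_i a_j}.$$

Both are ratio-weighted, so whether the selected OTUs' abundances are
renormalized is immaterial (asserted by test). After min–max
standardization of each index over the sample set,

$$\mathrm{resistance} = \sqrt{\mathrm{CMTB}_\mathrm{stand}^2 +
                              \mathrm{CMRA}_\mathrm{stand}^2}
  \in [0, \sqrt{2}].$$

## OTU selection schemes

Samples differ in how their abundance is spread over OTUs, so
`compute_indices()` supports two ways of putting them on a common footing
before averaging (`selection_scheme()`):

- **cumulative**: each sample's most abundant OTUs up to a fixed cumulative
  relative abundance; default levels 0.75, 0.80, 0.85, 0.90. Ranking ties
  break by table order so the selection is deterministic.
- **random**: uniform draws of a fixed number of the OTUs present in the
  sample; default levels 300, 500, 700, 900 with 100 replicates. Indexes
  are computed per replicate and then averaged (not the other way around).
  Samples whose richness falls below a level are excluded from that level
  with a warning. One master seed drives per-sample, per-level substreams,
  so results do not depend on iteration order.

Min–max standardization is done within one scheme × level variant, over the
samples retained at that variant. `method_independence()` computes all
pairwise Pearson correlations of the per-sample index vectors across
variants; a high minimum says the indexes are a property of the communities
rather than of the selection procedure.

## The niche-model simulator

`scenario()` defines a generative model whose defaults emulate a
two-region field survey: 472 samples, a 2000-OTU pool, 9736 reads per
sample (a typical post-rarefaction depth), and six observed environmental
variables. Samples receive a latent gradient position $g_j$ from a
two-component Gaussian mixture (two climatically distinct regions,
means ±1.5, sd 0.8); the observed variables are linear loadings of $g_j$
plus Gaussian noise (sd 0.6), which reproduces the strong inter-variable
correlations of real edaphic/climatic data. Each OTU has a Gaussian niche
on the gradient — optimum $\mu_m$ (uniform over $[-3, 3]$), breadth
$\sigma_m$, peak intensity $A_m$ (lognormal, sdlog 0.5) — and sample $j$'s
counts are one multinomial draw of the fixed depth from the normalized
intensities $A_m \exp(-(g_j-\mu_m)^2 / 2\sigma_m^2)$. A multinomial at
fixed depth (rather than Poisson or negative-binomial) matches what a
rarefied table is; zeros arise naturally where a niche is far from a
sample.

Breadths are a two-component mixture: a generalist pool
($\sigma \sim U(1.5, 5)$, fraction 0.25 of OTUs) and a specialist pool
($\sigma \sim U(0.3, 1.2)$). The 25% generalist share reflects that
specialist taxa typically outnumber generalists in field classifications;
the truth table flags each OTU's ecotype at the fixed cut
$\sigma \geq 1.35$. Two presets are frozen:

- `scenario_recovery(seed = 42)` — 400 samples, 600 OTUs, depth 5000: the
  benchmark used by the test suite and the acceptance script. The sizes
  keep a full-pipeline run in seconds while leaving recovery statistics
  stable across seeds.
- `scenario_richness_gradient(seed = 42)` — 200 samples, 600 OTUs, depth
  5000, with specialist optima drawn with density increasing along the
  gradient. Samples further along the gradient can recruit from a larger
  specialist pool, so richness rises by specialist addition and CMTB falls:
  a built-in negative richness–CMTB association against which the
  downstream statistics are checked.

What the simulator does **not** emulate: taxonomic or phylogenetic
structure, compositional sequencing bias, chimeras or other read-level
artifacts, multi-dimensional niches (niches live on one latent axis; the
six observed variables are correlated projections of it), and
species interactions. Passing recovery tests therefore demonstrates that
the estimators recover the model's truth under the model's assumptions —
it does not validate the space-for-time assumption itself on field data.

## Numerical choices and degenerate inputs

- **Weights**: TB accepts raw counts or relative abundances identically
  (ratio invariance, tested). Community means use the original
  within-sample relative abundances of the selected OTUs.
- **Quantiles**: type 7 everywhere, thresholds compared with $\geq$ / $\leq$.
- **Rarefaction** (`rarefy()`): one multivariate-hypergeometric draw per
  sample (delegated to `vegan::rrarefy`), seeded; samples under the target
  depth error by default and are dropped only on `drop_short = TRUE`,
  because silently losing samples would corrupt the min–max
  standardization downstream.
- **Spearman ties**: average ranks, the standard convention.
- **Min–max with zero range**: an error naming the degenerate index — a
  survey in which every community has identical CMTB has no standardized
  form.
- **AIC selection** (`fit_best()`): Gaussian-likelihood AIC; only
  differences matter, and the selection is invariant to the additive
  likelihood constant (tested against a second convention). When both
  models fit to numerical precision (relative RSS below 1e-10 of the total
  sum of squares), the AIC of a near-zero RSS is floating-point noise, so
  the simpler linear model is selected.
- **Cohen's d**: pooled (n−1) standard deviation; sign preserved so the
  direction of a regional contrast is readable.
- **Annual climate variation** (`climate_cv()`): per-year CV (sample sd /
  mean of the 12 monthly values), averaged over years.

## Problem sizes

The test suite and `scripts/acceptance.R` run the full pipeline on the two
presets above (400 × 600 and 200 × 600 tables); these sizes were chosen so
that a complete run — simulation, TB, the full RA matrix, both selection
schemes with 100 random replicates, and the gradient statistics — finishes
in well under a minute. At the default scenario's 600-OTU pool, attainable
richness stays below the upper random-selection levels (700 and 900), so
those variants drop out of the method-independence comparison there; with
the constructor's study-scale defaults (2000 OTUs, depth 9736) all four
random levels are populated.

## Known limitations

RA is cross-sectional: it reads asynchrony from space, not from time
series, and temporal synchrony metrics are out of scope. TB inherits the
usual caveats of occupancy-based niche estimates — an OTU rare for reasons
unrelated to environment (dispersal limits, biotic exclusion) will look
like a specialist. The resistance potential is a ranking device over the
surveyed communities (its standardization is survey-relative), not an
absolute quantity comparable across studies.
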