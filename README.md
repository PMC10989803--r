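# commresist

Community resistance potential for microbial communities surveyed along
environmental gradients.

Soil (and other) microbial surveys routinely ask whether species-richer
communities are also more tolerant of environmental disturbance. `commresist`
implements a pair of community-level indexes that make that question
quantitative, starting from nothing more than an OTU count table and a
matching table of environmental measurements:

- **Tolerance breadth (TB)** of OTU *m*: with abundances *a_j* over the
  samples the OTU occupies and z-scored environment vectors *x_j*, the
  weighted centroid is *C = Σ a_j x_j / Σ a_j* and

  *TB_m = Σ a_j z_j / Σ a_j*, with *z_j = ‖x_j − C‖*.

  Large TB means the OTU reaches appreciable abundance across disparate
  environments — a putative habitat **generalist**; small TB marks a
  **specialist**. Classification uses quantiles of the TB distribution
  (generalists at or above the *q* quantile, specialists at or below
  *1 − q*).
- **CMTB** (community mean tolerance breadth): the relative-abundance-
  weighted mean TB of a sample's (selected) OTUs.
- **Response asynchrony** *RA_ij = −ρ_ij*, the negated Spearman correlation
  of OTUs *i* and *j*'s relative-abundance profiles across all samples:
  +1 = fully compensatory, −1 = fully synchronous.
- **CMRA** (community mean response asynchrony):
  *Σ_{i<j} a_i a_j RA_ij / Σ_{i<j} a_i a_j* over distinct OTU pairs in a
  sample.
- **Resistance potential**: after min–max standardization of CMTB and CMRA
  over the sample set, *√(CMTB²_stand + CMRA²_stand)* ∈ [0, √2].

Because both indexes depend on which OTUs are taken to represent a sample,
two selection schemes put samples on a comparable footing — the most
abundant OTUs up to a cumulative relative abundance (levels 0.75–0.90), or
random draws of a fixed richness (300–900 OTUs, 100 replicates, averaged) —
and `method_independence()` verifies the resulting indexes agree across all
scheme × level variants.

A Gaussian niche-model simulator (`scenario()`, `simulate_community()`)
generates communities with known per-OTU niche optima and breadths on a
two-region latent gradient, so every estimator can be validated by parameter
recovery without any field data.

## Worked example

```r
library(commresist)

sim <- simulate_community(scenario_richness_gradient(seed = 42))
tb  <- tolerance_breadth_all(sim$counts, standardize_env(sim$env))
head(tb, 3)
#>    otu_id       tb n_occupied
#> 1 OTU0001 1.399204        111
#> 2 OTU0002 1.577618        154
#> 3 OTU0003 1.812388        185

cls <- classify_ecotypes(tb, quantile = 0.75)
table(cls$label)
#> generalist    neither specialist
#>        150        300        150

ind <- compute_indices(sim$counts, sim$env,
                       selection_scheme("cumulative", levels = 0.9))
head(ind[, c("sample_id", "richness", "cmtb", "cmra", "resistance")], 3)
#>   sample_id richness     cmtb       cmra resistance
#> 1      S001      417 1.892817 -0.2096352  0.8799694
#> 2      S002      283 1.952590 -0.5344375  0.6381123
#> 3      S003      354 1.924119 -0.4088651  0.6802909

fit_best(ind$richness, ind$cmtb)
#> Linear vs quadratic fit (n = 200)
#>   linear:    AIC = -602.00, R2 = 0.801
#>   quadratic: AIC = -600.02, R2 = 0.801
#>   selected: linear
```

`tb` holds each OTU's tolerance breadth and occupancy; the classification
splits the 600-OTU pool into the top and bottom TB quartiles. Each row of
`ind` is one sample: its observed richness, raw and standardized indexes,
and resistance potential. The fit shows what this preset is engineered to
produce — community mean tolerance breadth declining as richness rises
(here the decline is close to linear, so the AIC penalty favors the linear
model), because richer communities carry a larger share of narrow-niche
specialists.

A thin command-line wrapper around the same functions ships in
`inst/cli/commresist` (subcommands `simulate`, `tb`, `classify`, `ra`,
`indices`, `analyze`).

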