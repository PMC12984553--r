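# specoccu

Community analysis of **root fungal endophytes (RFEs) across plant
functional groups (PFGs)** — grasses, legumes, dicot and monocot forbs.
The package is aimed at microbial ecologists who have an OTU count
table, sample metadata, host trait measurements and FUNGuild-style
guild annotations, and want to answer three questions:

1. Do the functional groups carry different endophyte communities
   (alpha-diversity GLMs, Bray–Curtis ordination, pairwise PERMANOVA)?
2. Which host traits explain the turnover (random-forest regression of
   pairwise community dissimilarity on trait distances, with %IncMSE
   importance and permutation significance)?
3. Which OTUs mark each group (the SPEC-OCCU statistic)?

## The marker statistic

For OTU *j* and group *H*, with x̄*ⱼH* the mean rarefied count of *j*
over the samples of *H*:

```
specificity(j, H) = x̄ⱼH / Σ_H' x̄ⱼH'          (sums to 1 across groups)
occupancy(j, H)   = #{samples of H with xⱼ > 0} / #{samples of H}
```

An OTU is a **marker** of *H* when both are ≥ 0.7 (inclusive) — the
Dufrêne–Legendre specificity/fidelity pair with a dual threshold.
PERMANOVA uses Anderson's pseudo-F computed from pairwise squared
distances with label-permutation p-values; importance is the unscaled
percentage increase in out-of-bag MSE with an rfPermute-style
permuted-response null.

A fully seeded synthetic community generator (`simulate_dataset()`)
reproduces the survey design — 45 species (32/6/4/3 per group), three
replicates each, uneven sequencing depths, planted marker OTUs, and
nitrogen-driven community turnover — so every stage of the pipeline is
validated against known ground truth. See the vignette in
`vignettes/endophyte-community-analysis.Rmd` for the model and every
tunable parameter.

## Worked example

```r
library(specoccu)

ds <- simulate_dataset(sim_config(seed = 7, force_marker_occupancy = TRUE))
ds
#> Synthetic root-endophyte survey
#>   135 samples x 2000 OTUs; 45 species in 4 groups (DF:32, G:6, L:4, MF:3)
#>   planted markers per group: 5 (boost 20.0)

an <- analyze_dataset(ds, seed = 7, n_permutations = 999,
                      n_trees = 200, n_null_reps = 100)
an
#> Root-endophyte community analysis
#>   rarefied to depth 2017; 135 samples x 2000 OTUs
#>   richness letters: DF=a G=a L=a MF=a
#>   PERMANOVA: F = 2.44, R2 = 0.053, p = 0.001
#>   pairwise PERMANOVA: 6 of 6 pairs significant (BH 0.05)
#>   top predictor: nitrogen (%IncMSE 29.5, p = 0.0099)
#>   marker OTUs: 21 (DF:5, G:5, L:6, MF:5)

an$importance
#> Random-forest importance (200 trees, mtry 2, 100 null reps)
#>   (**: p < 0.01; *: p < 0.05; ns: not significant)
#>       predictor inc_mse  p_value significance
#> 1      nitrogen  29.490 0.009901           **
#> 2      cn_ratio  11.237 0.009901           **
#> 3  root_biomass   8.150 0.029703            *
#> 4   root_length   5.422 0.138614           ns
#> 5 water_content   5.178 0.089109           ns
#> 6     abundance   2.509 0.237624           ns
```

Reading the output: all samples were rarefied to the minimum depth
(2,017 reads). Richness does not differ among groups at this effect
size (all groups share letter "a"), but community *composition* does:
the one-way PERMANOVA partitions 5.3% of the distance variance among
groups (p = 0.001), and every group pair separates. Nitrogen
concentration — the trait that actually drives turnover in the
generator — tops the importance ranking at the smallest attainable
permutation p (1/101). The marker filter recovers 21 marker OTUs: the
20 planted ones (5 per group) plus one emergent nitrogen-driven legume
specialist.

```r
an$markers
#> Marker OTUs per group:
#>   DF: 5 markers (4.8% of group sequences)
#>   G: 5 markers (5.5% of group sequences)
#>   L: 6 markers (4.3% of group sequences)
#>   MF: 5 markers (4.7% of group sequences)
```

All tables read and write as plain TSV (`read_otu_table()`,
`write_dataset()`, …), so real survey data drops into the same
pipeline via `read_dataset()` or the individual readers.

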