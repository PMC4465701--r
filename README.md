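# commphy

Community-phylogenetics and trait-convergence analysis for presence/absence
metacommunities sampled along environmental and spatial gradients — built
around the kind of question a field herpetologist asks of a set of snake
community surveys: *do habitat filtering and latitude structure which
lineages and which morphologies co-occur?*

The package implements four linked analyses over a rooted phylogeny
(node-count distances; branch lengths are ignored), a sites × species 0/1
composition table with habitat (`forest`/`non_forest`) and latitude
metadata, and a species × traits table of 8 morphometric measurements
(SVL, TL, CAM, HL, HW, HH, VS, SS, plus a derived allometric `robustness`):

1. **Per-site phylogenetic structure.** Net relatedness and nearest taxon
   indices against each site's *regional pool*,
   `NRI = −(MPD_obs − mean_null)/sd_null` (NTI analogous with MNTD), with
   richness-constant tip-label randomization nulls (9,999 by default),
   exhaustive enumeration for small pools, and `|z| > 1.96` significance.
2. **Phylogenetic fuzzy-weighting.** Similarities `s = 1 − d/d_max` are
   column-normalized into fuzzy weights Q; `P = Q W_rel` is the
   phylogeny-weighted composition (columns sum to 1). PCoA of Bray–Curtis
   dissimilarities among P's columns yields PCPS axes; the number of axes
   kept is the one maximizing the pooled db-RDA F against the predictors.
3. **Trait convergence and d-separation.** Community-weighted mean matrix
   `T = W_rel B̂` on ranged traits; matrix correlations ρ(TE), ρ(PT) and the
   partial ρ(TE.P) with species-level permutation nulls; exhaustive search
   for the trait subset maximizing convergence; a verdict separating
   phylogenetic niche conservatism from phylogeny-independent convergence.
4. **Variation partitioning.** OLS of indices and PCPS axes on the habitat
   dummy + latitude, and two-set partitioning into unique/shared/residual
   fractions (raw and adjusted R², both reported).

A ground-truthed synthetic generator (`simulate_dataset()`, preset
`snakelike_params()`: 182 species, 12 sites, richness 9–61, latitudes
3.1–29.7°S) provides Brownian traits with a tunable habitat effect β, a
habitat filter φ acting on a conserved affinity, and clade ranges displaced
along latitude by γ — so every stage is testable with known truth.

## Worked example

The package ships the per-community summary of a 12-site Brazilian snake
survey (`snake_survey()`: site, vegetation, habitat, latitude, richness and
published NRI/NTI values). Regressing NRI on habitat and latitude:

```r
library(commphy)
sv <- snake_survey()
ols_fit(sv$NRI, sv[, c("habitat_forest", "latitude")])
#> OLS: R2 = 0.9023 (adj 0.8806), F(2,9) = 41.568, p = 2.846e-05

varpart_two(sv$NRI, data.frame(latitude = sv$latitude),
            data.frame(habitat = sv$habitat_forest))
#> variation partitioning (a = unique set 1, b = shared, c = unique set 2, d = residual)
#>   raw:      a = 0.747, b = 0.051, c = 0.104, d = 0.098
#>   adjusted: a = 0.810, b = -0.032, c = 0.103, d = 0.119
```

Habitat and latitude together explain ~90% of the variation in NRI;
latitude alone carries ~81% (adjusted form) and habitat ~10% — communities
at higher latitude, and in non-forest vegetation, are the more
phylogenetically clustered ones, while NTI shows no structure
(R² = 0.164, p = 0.45).

The full pipeline on a synthetic dataset with a strong filter:

```r
ds  <- simulate_dataset(snakelike_params(seed = 7, beta = 2, phi = 2, gamma = 1))
run <- run_all(ds$phylogeny, ds$metacommunity, ds$traits,
               analysis_config(n_randomizations_structure = 999,
                               n_permutations_convergence = 999,
                               n_permutations_dsep = 499, seed = 7))
run$convergence$rho_TE
#> matrix correlation rho = 0.711, p = 0.003 (999 permutations, species scheme)
run$convergence$verdict
#> [1] "convergence_independent_of_phylogeny"
```

`run_all()` writes per-stage CSVs (each with a metadata header recording
seed and parameters) and a manifest when given `out_dir`.

The numbered drivers under `analysis/` run the same stages as a narrative
workflow — `01_simulate.R` writes a ground-truthed dataset under
`results/synthetic/`, `02_survey_regressions.R` reproduces the regression
and partitioning above, and `03`–`05` run structure, PCPS and convergence
on the synthetic data.

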