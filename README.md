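# landgea

Range-wide adaptation analysis for non-model species: genotype–environment
association with genomic-inflation calibration, gradient-forest allelic
turnover, genomic offset under future climate, and seed-source similarity
mapping — with a synthetic-data generator so the whole pipeline is testable
end to end without any downloads.

## Who this is for

Landscape genomicists and restoration practitioners who have (or can
simulate) a biallelic SNP matrix for individuals sampled across a species
range, plus environmental raster layers, and who want to answer:

- Which loci are putatively adaptive to which environmental variables,
  after correcting for population structure?
- How does adaptive genomic composition turn over along environmental
  gradients, and where does it deviate from neutral structure?
- How much genomic change would local populations need under a future
  climate scenario (genomic offset), and where should seed for a given
  restoration site be sourced (genomic similarity)?

## The models at the core

**Structure.** Sparse nonnegative matrix factorization of the one-hot
genotype matrix estimates admixture proportions `Q` and ancestral allele
frequencies `G`; the number of ancestral populations `K` is chosen by
masked cross-entropy (lowest value, or the entry to a <1% plateau).

**GEA.** A latent factor mixed model `Y = x βᵀ + U Vᵀ + E` gives per-SNP
Z-scores for each environmental variable; factors are estimated by SVD with
the environmental direction projected off, so they absorb structure without
stealing the environmental effect. The genomic inflation factor

    λ = median(Z²) / χ²₁(0.5)

recalibrates P-values (`P = Pr[χ²₁ > Z²/λ]`); Benjamini–Hochberg yields
Q-values, and SNPs with `|Z| > 2` and `Q < 0.01` for at least one variable
are classified putatively adaptive.

**Turnover / offset.** Per-SNP regression forests (500 trees) on
environmental + PCNM spatial predictors are aggregated — split improvements,
density-standardized and R²-weighted — into monotone allelic-turnover
functions `f_v(x)`. The genomic offset of a grid cell between current
environment `x` and future environment `x'` is

    offset = sqrt( Σ_v ( f_v(x'_v) − f_v(x_v) )² ),

min-max scaled across all scenarios of a run. Seed-source similarity
reverses the min-max-scaled turnover distance between a restoration site's
*future* conditions and every cell's *current* conditions (1 = best match).

## Worked example

The bundled demo simulates a 40×40 landscape (4 environmental layers), 18
populations × 10 individuals from 3 admixed ancestral components
(target FST 0.15), 240 neutral loci and 25 loci with a logistic cline on
the `temp1` layer (slope 3 per s.d.), 5% missing calls, and a future
scenario shifting temperature layers by +1 s.d.:

```r
library(landgea)
m <- run_pipeline(demo_config(out_dir = "demo_out", seed = 42), quiet = TRUE)
res <- attr(m, "results")
res$K
#> [1] 3
print(res$models$adaptive)
#> turnover_model (adaptive set): 23 SNPs (23 with R2 > 0), 9 predictors, 200 trees
#> importance: temp1=0.2965, PCNM2=0.08481, PCNM5=0.06313, PCNM3=0.04286, ...
sum(res$gea$adaptive_any)
#> [1] 23
round(res$gea$lambda, 2)
#> temp1 temp2 prec1 prec2
#> 13.84  9.14  3.39  1.87
```

Reading the output: cross-entropy selects the planted K = 3; all 23 SNPs
classified adaptive are truly planted loci (23/25 planted survive
filtering); the causal layer `temp1` leads the R²-weighted turnover
importance by ~3.5× over any other variable; λ well above 1 reflects the
(intentional) collinearity of environment and ancestry gradients in the
simulation — the calibration divides it out. The spatial predictors (PCNM)
ranking next is expected under isolation by distance. Downstream, the
scaled offset of the demo scenario averages ~0.40 over the range.

Per-stage outputs (filtered VCF, ancestry `Q` matrix, per-SNP Z/P/Q table,
turnover models as JSON, offset/similarity/Procrustes grids as ASCII
rasters) land in `demo_out/`, catalogued in `manifest.json` with md5
checksums; rerunning the same configuration reproduces the checksums.

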