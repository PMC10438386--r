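---
title: "Models and methods behind landgea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind landgea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`landgea` is a pipeline for range-wide adaptation analysis in non-model
species: from a SNP dosage matrix and a stack of environmental rasters it
estimates population structure, scans for gene–environment associations
(GEA), models allelic turnover along environmental gradients, and projects
genomic offset and seed-source similarity under future climate scenarios.
This vignette explains the statistical machinery, the choices we made where
the design was genuinely open, and what the synthetic-data generator does
and does not emulate.

## The analysis chain

1. **Filtering** (`filter_genotypes`, `impute_missing`, `ld_prune`): SNPs
   with more than 20% missing calls are dropped; minor allele frequency
   (MAF), computed on the remaining non-missing calls, must reach 1%;
   missing dosages are imputed from locality allele frequencies; finally a
   greedy scan removes one SNP of every pair with squared dosage
   correlation r² > 0.5 within a 5 kbp window. These defaults are the
   conventional GBS filtering thresholds for landscape-genomic scans.
2. **Structure** (`fit_snmf`, `select_k`): sparse nonnegative matrix
   factorization of the one-hot genotype matrix estimates admixture
   proportions Q and ancestral allele frequencies G; the number of
   ancestral populations K is chosen by masked cross-entropy.
3. **GEA** (`fit_lfmm_z`, `genomic_inflation`, `calibrate_and_fdr`,
   `classify_adaptive`): a latent factor mixed model yields per-SNP,
   per-variable Z-scores; the genomic inflation factor λ recalibrates the
   P-values; Benjamini–Hochberg correction yields Q-values; SNPs with
   |Z| > 2 and Q < 0.01 for at least one variable are flagged putatively
   adaptive.
4. **Turnover** (`fit_gradient_forest`, `project_turnover`,
   `procrustes_residuals`): per-SNP regression forests on environmental and
   PCNM spatial predictors are aggregated into monotone allelic-turnover
   functions, projected over the raster grid, summarized by PCA, and the
   adaptive and neutral projections compared by Procrustes residuals.
5. **Offset and similarity** (`genomic_offset`, `scale_offsets`,
   `variable_contributions`, `similarity_map`): the Euclidean distance in
   turnover space between current and future conditions is the genomic
   offset; reversing min-max-scaled turnover distances between a
   restoration site's future conditions and every cell's current conditions
   gives the seed-source genomic-similarity map.

`run_pipeline()` sequences all stages from one (YAML) configuration and
writes a manifest with per-output md5 checksums; deterministic stages
reproduce identical checksums on rerun.

## Sparse nonnegative matrix factorization of ancestry

Genotypes are one-hot encoded: each SNP contributes three 0/1 columns
indicating dosage 0, 1, 2, giving a matrix D (individuals × 3·SNPs). We
factor D ≈ QH with Q ≥ 0 (rows on the probability simplex) and H ≥ 0,
minimizing

$$\lVert D - QH\rVert_F^2 \;+\; \alpha \lVert H\rVert_F^2
  \;+\; \gamma \lVert Q\mathbf{1} - \mathbf{1}\rVert^2 ,$$

by multiplicative updates, which keep the penalized loss non-increasing.
The simplex constraint on Q is enforced softly through the γ-augmented
column and made exact by one final renormalization. α defaults to 10, the
conventional order of magnitude for this estimator; it is exposed in the
configuration. Ancestral alternate-allele frequencies are recovered from
the genotype-probability triples of H, and K = 1 is special-cased to its
closed form (Q all ones, G the global allele frequencies).

**Model choice.** A random 5% of genotype entries is masked per repetition
(their one-hot triples replaced by locus marginals during fitting); the
cross-entropy is the mean negative log probability of the masked dosages
under binomial(2, QG). The chosen K is the argmin of the best-of-`reps`
cross-entropy curve unless the curve plateaus first: when moving from K to
K+1 improves cross-entropy by less than 1% (relative), K is selected. The
1% tolerance makes the qualitative "plateau" criterion deterministic.

**FST outliers.** Per SNP, FST is computed from G weighted by the mean of Q
(variance of component frequencies over total heterozygosity) and converted
to the statistic FST·(n−K)/(1−FST), treated as chi-square with K−1 degrees
of freedom — our reading of the standard ancestry-based outlier transform,
recorded as such in the documentation. The statistic is λ-recalibrated and
BH-corrected like the GEA scan.

## The latent factor mixed model and λ calibration

For each environmental variable x (standardized internally, so results are
invariant to affine rescaling), the model is

$$Y \;=\; x\beta^\top + U V^\top + E,$$

with K latent factors U absorbing neutral structure. We use the
deterministic least-squares/SVD formulation rather than an MCMC sampler:
the latent factors are the leading left singular vectors of the centered
genotype matrix *after projecting off the environmental direction*, and
β and its standard error come from per-SNP OLS on (1, x, U), giving
Z = β̂/se(β̂). Projecting x off before extracting factors matters: factors
taken from the raw genotype matrix absorb exactly the covariance axis that
a polygenic environmental response creates, driving the Z-scores of every
true signal toward zero. With the projection, U cannot steal the
environmental effect; whatever structure-environment collinearity remains
inflates the null Z-scores *uniformly*, which is precisely what the
genomic inflation factor

$$\lambda \;=\; \frac{\mathrm{median}(Z^2)}{\chi^2_1(0.5)}$$

is designed to remove: calibrated P-values are the upper-tail χ²₁
probability of Z²/λ (the χ²₁ median is computed from the inverse CDF at
run time, ≈ 0.4549). One λ is computed per environmental variable. λ can
be far from 1 when environment and ancestry gradients are collinear — that
is the diagnostic working as intended, not a failure. With K = 0 the
Z-scores reduce exactly to simple-regression t-statistics, which the tests
use as an oracle.

`reps` repetitions with the per-SNP median Z are retained for interface
compatibility with stochastic estimators; this estimator is deterministic,
so the median is a no-op. Two-sided tests are used throughout, as the
|Z| > 2 classification rule implies.

## Gradient-forest allelic turnover

For every SNP a regression forest (500 trees by default,
mtry = ⌈p/3⌉, minimum node size 5) predicts allele frequency
(dosage/2) from the environmental variables plus PCNM spatial
eigenvectors. The forest engine is implemented in C++ in this package
because the turnover aggregation needs the *location and improvement of
every split*, which established forest packages do not expose; it records
per-split (variable, threshold, SSE improvement), out-of-bag predictions,
and permutation importance. Permutation importance is conditional:
a variable's values are permuted within observation groups formed by
median-splits of its correlated partners (|r| > 0.5, up to two partners),
a coarse-grid approximation to conditional permutation that limits the
importance leakage between collinear predictors. One shared permutation
per variable per forest is used (the scikit-learn convention); aggregation
over hundreds of SNP forests stabilizes the estimate.

SNPs with out-of-bag R² ≤ 0 are excluded. Per included SNP, nonnegative
permutation importances are scaled to sum to that SNP's R²; the
R²-weighted importance of a variable is the mean of these over SNPs. The
turnover function of a variable is the cumulative distribution of split
improvements along it — each split's improvement divided by the local data
density (equal-width bins, at least two, derived from the
`max_splits(p) = log2(0.368 p)/2` partition-depth control) — aggregated
over SNPs with R² weights and scaled so the total height equals the
variable's importance. The functions are non-decreasing, zero at the
predictor minimum, and evaluated elsewhere by linear interpolation with
clamping outside the training range.

Projection maps every masked-in raster cell through the turnover
functions; PCA over the mask summarizes the transformed vectors (PC1–PC3).
PCNM eigenvectors are interpolated from the sampling sites to the grid by
inverse-distance-squared weighting. The adaptive-SNP and neutral-SNP
projections are superimposed by orthogonal Procrustes rotation
(translation, rotation/reflection, isotropic scaling, via `vegan`); the
per-cell residual distance maps where adaptive structure departs from
neutral structure. The neutral set is the complement of the
adaptive-classified set among filtered SNPs.

**PCNM details.** Distances beyond the truncation (by default the longest
minimum-spanning-tree edge) are replaced by four times the truncation, the
standard construction; of the positive-eigenvalue vectors we keep the half
with the *largest* eigenvalues — the broadest spatial scales — since the
selection criterion for "half" is otherwise unstated. Planar coordinates
are used for the synthetic grids.

## Offset, scaling, and seed-source similarity

The genomic offset of a cell is the Euclidean distance between its current
and future turnover vectors. We apply the square root (the named metric);
`sqrt = FALSE` preserves the raw sum of squares, which is monotonically
equivalent. Offsets are min-max scaled with constants pooled across *all*
scenarios of a run, so maps are comparable across SSPs and periods; a
degenerate all-equal collection scales to 0 with a warning.
`variable_contributions` decomposes each cell's squared offset into
per-variable fractions.

For seed-source matching, the restoration site's predictor vector under
the chosen future scenario is transformed through the (adaptive-SNP)
turnover model and compared to every cell's *current* turnover vector;
distances are min-max scaled over the mask and reversed, so similarity 1
marks the best current seed sources for the site's future conditions. The
direction — future site onto current landscape — follows the tool this
mirrors; the reverse comparison can be assembled from the same primitives.

## The synthetic-data generator

The generator exists so that every stage can be tested against known
truth, offline. It emulates:

- **Environment**: Gaussian-smoothed random fields (autocorrelation scale
  in cells), standardized per layer, with the *realized* inter-layer
  correlation matrix made exactly equal to the requested one by
  orthogonalizing the fields and recolouring with the Cholesky factor.
  Future scenarios add per-layer shift fields; the default shifts
  temperature-like layers by +1 s.d., emulating directional warming.
- **Sampling**: populations at distinct grid cells, individuals sharing
  their locality's coordinates — locality-based field sampling at the
  scale of the real studies this package targets (tens of localities,
  ~10 individuals each).
- **Neutral structure**: Balding–Nichols component frequencies with
  admixture. Components are anchored at well-separated population cells
  (greedy maximin) with distance-decay admixture plus noise, giving
  isolation-by-distance-like, spatially smooth structure in which each
  component dominates somewhere — without this, a requested "true K" may
  simply not be realized in the data. Because admixture dilutes
  differentiation, the component-level Balding–Nichols parameter is
  analytically inflated by the realized admixture dispersion so that the
  realized multi-locus Weir–Cockerham FST across populations matches
  `target_fst` (the tests verify a ±0.05 band at 0.15).
- **Adaptive loci**: population allele frequencies follow a logistic cline
  in the standardized causal layer with the stated slope ("per
  environmental s.d."), random intercepts, binomial(2, p) sampling.
- **Missingness**: completely at random — sufficient to exercise the 0.2
  filter, though real GBS missingness is structured.

It does **not** emulate linkage disequilibrium decay, coalescent noise,
selection through time, or structured missingness; passing tests
demonstrate correctness of the statistical machinery under the stated
generative model, not performance guarantees on real GBS data.

## Numerical choices and degenerate inputs

- Zero-variance SNPs have r² defined as 0 in LD pruning (never NaN).
- MAF uses non-missing calls only; the filter order is missingness → MAF →
  imputation → LD pruning, and the earlier-position SNP of a correlated
  pair is kept (deterministic tie-break).
- Correlation pruning of environmental variables recomputes the matrix
  after every removal (the iterative greedy rule), removing from the worst
  pair the variable with the larger mean absolute correlation; ties remove
  the later column.
- A split threshold that lands exactly on a predictor's minimum (floating
  point) is nudged right by 10⁻⁹ of the range so turnover functions stay
  anchored at zero.
- Constant landscapes project to identical turnover vectors with all-zero
  PCA scores; all-equal offset collections scale to zero with a warning.
- All stochastic steps take explicit seeds; `run_pipeline` derives stage
  seeds from the master seed and logs them in the manifest.

## Problem sizes used by the test suite

The suite runs on simulated studies sized to the method, chosen once:
structure recovery uses 3 populations × 20 individuals × 1,000 loci with
K ∈ 1–5 and 2 repetitions; GEA calibration uses 10,000 null loci on 200
individuals; power and gradient-forest causality use 30 localities × 10
individuals (mirroring the real studies' 28–35 localities) with 500-tree
forests over 200 SNPs; the end-to-end demo is a 40 × 40 landscape with 18
populations and 265 loci. Repetition counts for K selection (2–3) are
below the 10 used on real data because the synthetic fits are far better
conditioned; the plateau rule and per-K best-of-reps logic are identical.

## Known limitations

- The GEA estimator is the deterministic ridge/SVD latent-factor
  formulation; the MCMC variant of the same model is out of scope. With
  strong environment–structure collinearity its λ can be large, and power
  then rests on the calibration.
- The conditional-permutation approximation uses a coarse two-partner
  median grid; with many highly collinear predictors, importance can still
  leak within a cluster (the correlation pruning step is the first line of
  defense).
- Turnover functions are step functions smoothed only by linear
  interpolation; with few SNPs or trees they are coarse.
- The raster model is a single planar grid (headered ASCII interchange);
  map projections and multi-resolution mosaics are out of scope —
  rasters must be co-registered (see `resample_to_grid`) before use.
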