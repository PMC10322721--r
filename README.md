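# receptorgradients

Analysis of the large-scale organisation of neurotransmitter-receptor
densities across the cortical sheet, built as a tested, reusable R
pipeline. The package covers the full chain from quantitative in vitro
autoradiography densitometry to statistical maps:

- **Densitometry**: standards of known radioactivity are converted to
  binding-site concentrations via
  `C_b = R / (E · B · W_b · S_a) · (K_D + L) / L`
  (counter efficiency `E`, decay constant `B`, protein weight `W_b`,
  specific activity `S_a`, dissociation constant `K_D`, incubation ligand
  concentration `L`), a monotone piecewise-cubic calibration curve
  linearises 8-bit autoradiographs, and laminar profiles / replicate
  coefficients of variation summarise per-area densities.
- **Map algebra**: vertex-area-weighted parcel averaging, row-stochastic
  fractional overlap between parcellations with overlap-weighted
  resampling, and conversion of raw densities (fmol per mg protein) to
  densities per neuron using a neuron-density map and the 8 % protein mass
  fraction of brain tissue.
- **Receptor gradients**: column z-scoring and the singular value
  decomposition `X_norm = U S V^T` with PC scores `Z = U S`; variance
  fractions, receptor fingerprints, the two-dimensional "receptor space",
  and the leave-one-receptor-out **gradient dependence**
  `g = 1 − ρ²`, where `ρ` correlates a PC's scores with the first-PC
  scores of the deflated matrix after deleting one receptor column.
- **Spatially aware inference**: variogram-matched surrogate maps
  (permute → kernel-smooth → amplitude-adjust) give correlation p-values
  that respect spatial autocorrelation, with Bonferroni adjustment over a
  declared comparison family.
- **Functional embedding**: z > 3.1 binarization of activation maps, Dice
  coefficients against 20 percentile bins of a gradient map, and
  functional receptor fingerprints.
- **Gene expression**: a microarray-sample-to-parcel pipeline (gene-id
  probe filter, 2 mm sample assignment, within-sample z-scoring,
  low-similarity sample removal, 40 %-of-areas probe filter, scaled
  robust sigmoid normalisation per donor, nearest-sample fallback,
  representative-probe selection).

A first-class synthetic-data module generates every input with planted
ground truth (a toy spherical cortex, receptor matrices with known
gradients, smooth maps, functional z-maps, donor-structured sample sets),
so each stage supports parameter-recovery testing without any downloads.

## Worked example

```r
library(receptorgradients)

cortex <- generate_toy_cortex(n_areas = 60, mesh_resolution = 4, seed = 2)
truth  <- planted_ground_truth(cortex, noise_sd = 0.2, seed = 7)
mats   <- generate_receptor_matrix(cortex, truth)

pn  <- per_neuron(mats$raw, truth$neuron_density)
fit <- receptor_pca(zscore_columns(pn))
glance(fit)
#> # A tibble: 1 × 8
#>   var_pc1 var_pc2 var_pc3 var_pc4 var_pc5 var_top5 n_areas n_receptors
#>     <dbl>   <dbl>   <dbl>   <dbl>   <dbl>    <dbl>   <int>       <int>
#> 1   0.903  0.0544 0.00862 0.00607 0.00528    0.978      60          14

dep <- gradient_dependence(fit, n = 2)
dep[which.max(dep$g), ]
#> # A tibble: 1 × 4
#>      pc receptor    rho     g
#>   <dbl> <chr>     <dbl> <dbl>
#> 1     2 5HT1A    -0.863 0.255
```

The first PC captures 90 % of the variance of this synthetic per-neuron
matrix — a shared gradient that all receptors load on positively, tracking
total receptor density per neuron. The second gradient's dependence table
singles out the serotonin 5-HT1A receptor, the planted driver of PC2:
removing it collapses the secondary gradient (`g = 0.26`) while removing
any other receptor barely perturbs it (`g < 0.01`).

Spatially corrected comparisons against another cortical map:

```r
D   <- distance_matrix(cortex)
pc1 <- tibble::tibble(area_id = rownames(fit$scores), value = fit$scores[, 1])
cmp <- generate_smooth_map(cortex, correlation_length = 20, seed = 9)
ens <- make_surrogates(pc1, D, n_surr = 1000, seed = 3)
corrected_correlation(pc1, cmp, ens)
#> # A tibble: 1 × 5
#>        r p_spatial     n  ci_lo  ci_hi
#>    <dbl>     <dbl> <int>  <dbl>  <dbl>
#> 1 -0.212     0.306    60 -0.442 0.0441
```

`run_pipeline(pipeline_config(seed = 1))` executes all stages end to end
and writes every stage table plus an MD5 manifest to the output directory.

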