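---
title: "Receptor gradients across the cortical sheet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor gradients across the cortical sheet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(receptorgradients)
```

## The scientific problem

Neurotransmitter receptors mediate nearly all interactions between
cortical neurons, and their densities vary systematically across the
cortical sheet. Quantitative in vitro autoradiography measures these
densities — a panel of 14 receptor types spanning glutamate, GABA,
acetylcholine, serotonin, noradrenaline and dopamine systems — area by
area, in units of fmol of binding sites per mg of protein. Once those
densities are normalised by neuron counts and assembled into an
area-by-receptor matrix, a small number of principal components describe
most of the spatial variation: a dominant gradient on which every
receptor loads positively (it tracks the total receptor density per
neuron and runs from sensory toward higher cognitive cortex), and a
secondary gradient driven largely by the serotonin 5-HT1A receptor. This
package implements that analysis chain end to end, together with the
statistics needed to interpret it honestly: a leave-one-receptor-out
dependence measure for gradients, spatial-autocorrelation-aware
correlation tests, an embedding of functional activation maps into
gradient space, and a microarray-to-parcel gene-expression pipeline for
gene-receptor comparisons.

## Densitometry model

Co-exposed standards of known radioactivity `R` (counts per minute) are
converted to binding-site concentrations by

$$C_b = \frac{R}{E \, B \, W_b \, S_a} \cdot \frac{K_D + L}{L},$$

where `E` is the scintillation-counter efficiency, `B` the number of
decays per unit time and radioactivity, `W_b` the standard's protein
weight (mg), `S_a` the ligand's specific activity (Ci/mmol), `K_D` its
dissociation constant (nM) and `L` its incubation concentration (nM).
The first factor converts counts into mol of bound ligand per mg
protein; the saturation factor `(K_D + L)/L` extrapolates from the
occupied fraction at concentration `L` to the full binding-site
population. The formula is homogeneous of degree 1 in `R` and −1 in each
of `E`, `B`, `W_b`, `S_a` — the package's tests exercise exactly these
identities.

The gray-value-to-concentration calibration curve is a monotone
piecewise-cubic (Fritsch–Carlson) interpolant through the standards.
No functional form for the film response is imposed: monotone cubic
interpolation is exact at every standard, cannot oscillate, and is
standard practice for saturating film responses. Outside the calibrated
gray range the curve **clamps** to the nearest knot with a warning
rather than extrapolating — film saturates, and extrapolation beyond the
standards is unphysical. Total binding is treated as equivalent to
specific binding by default (non-specific binding is a small fraction
for the ligand protocols in question); an explicit
subtract-nonspecific mode can be layered on by calibrating on corrected
standards.

Laminar profiles operate on *rectified* 2-D patches (rows = cortical
depth from pial to white matter, columns = tangential position): each of
`n_bins` depth bins is the mean concentration over its row band. True
curvilinear traversal of folded cortex is deliberately out of scope; the
rectified simplification is documented rather than hidden. Replicate
quality control uses the coefficient of variation with the sample
(n−1) standard deviation, appropriate for 3–5 sections per area.

## From raw densities to gradients

Raw densities (fmol per mg protein) become densities per neuron via

$$\text{per-neuron}(a, r) = \text{raw}(a, r) \cdot
  \frac{f_{\text{protein}} \cdot 1000}{\nu(a)},$$

with `f_protein = 0.08` (the protein mass fraction of brain tissue) and
`ν(a)` the neuron density in neurons per gram. Because column z-scoring
absorbs any global constant, the gradients do not depend on
`f_protein` — a property the tests assert directly.

The gradients are the principal components of the column-z-scored matrix
`X_norm = U S V^T`, with per-area scores `Z = U S`, receptor loadings
`V`, and variance fractions `S_k² / Σ S_j²`. All `min(A, R)` components
are retained; no truncation heuristic is applied. Z-scoring uses the
sample (n−1) standard deviation; variance fractions are insensitive to
this choice and scores change only by a constant factor. Because
singular vectors have arbitrary sign, a reporting convention is fixed:
PC1 is oriented so its scores correlate positively with total density,
and each later PC so its largest-|loading| receptor loads positively.

**Gradient dependence.** How much does gradient `n` rely on receptor
`r`? Deflate the first `n − 1` components,
`X^{PCn+} = Z_{n+} V_{n+}^T`, delete column `r` — *without* re-centering
or re-scaling, since the deflated matrix is already in the model's
coordinates — project onto the first PC of the reduced matrix, and set
`g = 1 − ρ²` for the Pearson correlation `ρ` between those scores and
the original `Z_n`. Squaring makes `g` blind to the arbitrary signs of
PCs. `g ≈ 0` means the gradient survives the removal (for a duplicated
receptor it is zero to machine precision); `g → 1` means the gradient
collapses without that receptor. The test suite checks this operation
against an independent implementation built on eigen-decompositions of
cross-product matrices rather than the SVD.

## Spatially aware inference

Cortical maps are smooth, so area-level correlations cannot be tested
against an exchangeable (permutation) null. The package builds
variogram-matched surrogate maps from a source map and an inter-parcel
distance matrix: each surrogate permutes the source values, smooths the
permutation with a Gaussian distance kernel at each bandwidth in a grid
(including bandwidth 0), forms the affine mix
`√α · smoothed + √nugget · white noise` whose coefficients are fit by
weighted least squares so the candidate's empirical variogram matches
the source's (weights `1/γ²` control *relative* error across lags),
rescales exactly to the source mean and SD, and keeps the
bandwidth with the smallest weighted variogram residual. The empirical
variogram uses 25 equal-count lag bins over the 0–75th percentile of
distances; longer lags are poorly sampled and geometry-dominated.
Distances are Euclidean between parcel centroids — adequate at parcel
resolution, and noted as a design choice wherever reported. The
two-tailed p-value is the add-one exceedance count
`p = (1 + #{|r_null| ≥ |r|}) / (1 + n_surr)`, never exactly zero;
1,000 surrogates are the default and 100 the floor. Bonferroni
adjustment multiplies by the declared number of planned comparisons.

Calibration is verified empirically: on 200 independent pairs of smooth
null maps (Gaussian random fields with 20 mm correlation length on a
60-area cortex, 500 surrogates each) the type-I rate at α = 0.05 falls
within [0.02, 0.10], and the corrected p-values are stochastically
larger than naive permutation p-values on structured nulls — the
correction concedes to autocorrelation exactly as intended.

## Functional embedding and gene expression

Functional activation z-maps are binarized at the strict threshold
z > 3.1. The mask's position along a gradient is summarised by Dice
coefficients against 20 equal-count percentile bins of the
vertex-painted gradient map (bin sizes differ by at most one; ties
break by stable vertex order). The 20-bin Dice profile is reduced to a
scalar coordinate by the **Dice-weighted bin centroid**
`Σ b · Dice_b / Σ Dice_b`; an argmax-bin alternative is available. The
centroid was chosen because it degrades gracefully for masks spanning
several bins and is exact for symmetric profiles; this reduction is a
package decision, made once and configurable. Receptor maps are painted
piecewise-constant from areas onto vertices; functional receptor
fingerprints are vertex-area-weighted means over the mask. Network
summaries pool vertex values per cognitive network, excluding the
limbic network (flagged for areas with > 0.5 limbic overlap — the
threshold is a package decision, since only the exclusion itself is
conventional).

The gene-expression pipeline runs in a fixed, logged order: gene-id
probe filter → sample-to-vertex assignment (samples > 2 mm from the
mesh dropped; nearest-vertex assignment with one sample per vertex,
collisions resolved in stable donor/sample order) → z-scoring across
probes within samples → removal of samples whose within-donor
similarity falls below median − 3 × scaled MAD (the "exceptionally low
similarity" rule made precise; configurable) → probe filter requiring a
present call in at least 40 % of sampled areas (inclusive bound; the
denominator is areas containing at least one assigned sample) → scaled
robust sigmoid per donor across areas
(`y = 1/(1 + exp(−(x − median)/(IQR/1.35)))`, then min–max to [0, 1];
invariant under positive affine transforms) → equal-weight donor
averaging → representative-probe selection (2 probes: higher
across-area variance; ≥ 3: highest mean correlation with the others;
ties by probe id). "Significant expression" is modelled by the
present/absent call matrix. Areas without a present-call sample fall
back to the nearest present-call sample per vertex, averaged over the
area's vertices, with per-cell provenance recorded.

## What the synthetic generators emulate — and what they do not

The toy cortex is a subdivided-icosahedron sphere with geodesic-Voronoi
parcels grown from farthest-point-sampled seeds, giving contiguous
areas on a closed surface with no boundary artifacts. The receptor
generator plants `K` orthogonal smooth gradients (Gaussian random
fields over centroids, 20 mm correlation length): component 1 with
strictly positive loadings on all receptors, component 2 dominated by
the 5-HT1A column (|loading| at least 3× any other), Gaussian noise of
SD 0.2 in z-score units, and a neuron-density map with an exact 5-fold
range that covaries with the shared gradient — mirroring cortex, where
neuron-dense sensory areas impose common patterns on raw densities.
The raw matrix is constructed as the exact inverse of the per-neuron
normalisation, so the roundtrip identity holds to round-off. Microarray
sample sets add donor, probe and residual Gaussian offsets (SDs 0.5,
0.3, 0.2 in planted-map units) to planted per-area gene maps — exactly
the nuisance structure the normalisation stages exist to remove — with
coordinates jittered off the surface so the 2 mm rule has work to do.

These generators reproduce the *structure* of the real data, not its
content: no cortical folding, no film-physics beyond the calibration
curve, no haemodynamics. Passing recovery tests therefore demonstrates
that the pipeline's mathematics is correct and well-calibrated under
known ground truth; it does not by itself validate any neuroscientific
claim about real cortex.

## Numerical choices and problem sizes

All randomness flows from single integer seeds; sub-stage seeds are
derived by a fixed deterministic schedule, and every generator is a pure
function of its arguments. Degenerate inputs fail loudly: constant
receptor columns, constant maps, empty activation masks, zero IQRs and
zero neuron densities are errors naming the offending unit, never
silent repairs. Missing areas are dropped listwise before z-scoring and
pairwise in correlations, with counts reported.

The simulation sizes used by the tests and the acceptance script — a
60-area cortex (2,562 vertices), 14 receptors, 20 recovery seeds, 200
null map pairs with 500 surrogates, 6 donors × 100 samples × 40 probes
× 20 genes — were chosen once as the smallest configurations at which
every planted effect is comfortably identifiable; they are the
package's simulation design, stated here so results are reproducible at
the same sizes.

## Known limitations

- Parcel-level (not vertex-level) surrogates; Euclidean (not geodesic)
  centroid distances. Both are adequate at parcel resolution and flagged
  in reports.
- Laminar profiles assume rectified patches.
- The sample-to-surface registration chain of real microarray data is
  replaced by direct nearest-vertex assignment on the toy mesh; with
  real data, supply a precomputed sample-to-vertex table.
- Rotated or sparse PCA variants, diffusion-map connectivity gradients
  and cross-species surface alignment are out of scope; such maps are
  accepted as inputs.
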