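---
title: "Mapping brown-rot wood decay from hyperspectral NIR images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping brown-rot wood decay from hyperspectral NIR images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decaymap)
```

# The measurement and the model

Line-scan SWIR cameras image wood surfaces as cubes of
`rows × cols × bands` raw counts, here nominally 288 bands over
930–2,550 nm. Brown rot consumes wood carbohydrates while modifying
and relatively enriching lignin, so decay moves reflectance spectra
from cellulose/glucomannan absorption bands (≈1,474, 1,509, 2,062,
2,080, 2,342 nm) toward aromatic and carbonyl lignin bands (≈1,130,
1,648–1,670, 1,903, 2,240 nm). `decaymap` quantifies that movement on
two levels: per sample, by decomposing average spectra over a designed
decay experiment (ASCA), and per pixel, by PCA of image mosaics
followed by k-means classification of the score space.

## Preprocessing chain

Raw counts are despiked with a per-band 3×3 spatial median
(reflect-padded at the edges; the window is configurable but must be
odd), calibrated to reflectance with dark-current and white-reference
line-scan frames, `r = (raw − dark)/(white − dark)`, and clipped below
at `1e-6` (recorded in metadata; pixels where `white − dark ≤ 0` are
flagged invalid instead of clipped). For masking, reflectance spectra
are SNV-standardized — each spectrum centered and scaled to unit
standard deviation with the `n − 1` denominator, the common
chemometrics convention; the choice of denominator only rescales every
spectrum identically and nothing downstream depends on it — and a PCA
over the unfolded pixels flags background and saturated pixels whose
first-component score falls more than 4 robust standard deviations
(scaled MAD) from the median score. Saturation is defined as counts at
detector full scale. A fixed region of interest (by camera convention
281 × 301 pixels; clamped for smaller phantoms) is cut from the image
center, with the margins split by floor division when they are odd.
ROI pixels are converted to absorbance `A = log10(1/r)`, SNV-scaled,
and trimmed to 1,100–2,400 nm with both boundaries inclusive.

Two conventions in this chain were genuinely open and are exposed as
options: whether the analysis SNV standardizes absorbance or
reflectance (`snv_on`; default absorbance, which keeps the mixture
model linear in the component spectra), and whether the background PCA
runs per image or on a joint mosaic (implemented per image; background
detection is a per-acquisition property).

## ASCA of the factorial decay experiment

The average spectra of a balanced *position (7) × fungus (2) ×
replicate (5)* factorial are column-mean-centered into `X` and split
into main-effect and two-factor-interaction matrices by cell-mean
contrasts:

* main effect rows: level mean − grand mean;
* interaction rows: cell mean − both marginal level means + grand mean;
* residual: whatever remains.

On a balanced design these matrices are mutually orthogonal, so their
sums of squares partition the total exactly; `variation_table()`
reports each as a percentage summing to 100. Only balanced full
factorials are supported — weighted/ASCA+ variants for unbalanced data
are deliberately out of scope, and unbalanced designs error rather
than silently degrade.

Each effect matrix is decomposed by SVD into orthonormal spectral
loadings and sample scores; one component per effect is retained by
default since higher effect components are rarely interpretable for
low-rank effect matrices (a position main effect has rank ≤ 6). SVD
signs are fixed by making the largest-magnitude loading element
positive, so score plots are reproducible; all comparisons of loadings
should be made up to sign. Model residuals projected onto the effect
loadings (`S = T + E P`) display the natural within-level spread
around each effect's scores. Position-linked variation can be pooled
by `combine_effects()`, which simply adds the (orthogonal) matrices,
so the combined share is the sum of the parts.

### Permutation significance

Effect significance uses permutation of sample labels with the effect
sum of squares as statistic and the add-one estimator
`p = (#{SSQ_perm ≥ SSQ_obs} + 1)/(n_perm + 1)`, which cannot return
zero. The default scheme (`"free"`) permutes the data rows against the
design and recomputes the tested effect's SSQ from the factorial
decomposition. Under a pure-noise null this is exact for main effects
and interactions alike — the test suite verifies a rejection rate
statistically indistinguishable from the nominal 5% over 500 null
datasets. Its trade-off is conservatism for interaction tests when
large main effects are present, because free permutation mixes
main-effect variation into the interaction null. An alternative
residual scheme (`scheme = "residual"`) removes the other estimated
effects before permuting; it is more powerful but anti-conservative in
small designs (removing estimated effects deflates the permuted
statistic), so it is not the default. The headline default of 10,000
permutations matches standard practice for this experiment size; the
tests and the acceptance script use 199–1,999 permutations, which
resolve p-values to 1/200–1/2,000 at a fraction of the cost.

## Mosaic PCA and extreme-pixel removal

Retained ROI pixels of a sample series are unfolded row-major into one
pixels × bands matrix per fungus, mean-centered per mosaic (not per
sample — inter-sample contrast *is* the decay signal), and decomposed
by SVD. Variance shares are `σ_k²/Σσ²`. Four components are retained
by default, which on real wood data separate decay, earlywood/latewood
contrast and residual structure. Extreme pixels (cut fibers, residual
background) are removed by a single pass of the PC1 rule — more than 4
robust SDs from the median PC1 score — after which the PCA is
redetermined once; the threshold errors out if it would discard more
than 20% of the pixels, which indicates misconfiguration rather than
outliers. Scores are refolded into per-sample images through the
mosaic index map, with `NA` at excluded pixels.

## Decay classes

K-means with k = 3 runs on the PC1–4 score vectors. Initial centroids
are chosen deterministically: the point farthest (Euclidean) from the
center of the score cloud, then greedily the points maximizing the
minimum distance to the centroids already chosen, ties to the lowest
pixel index. Assignment uses the Pearson correlation between a pixel's
score vector and each centroid — following the field convention of
correlation-based matching of score profiles — while centroid updates
are arithmetic means; a pure-Euclidean mode exists and is verified
against a reference Lloyd implementation in the tests. Emptied
clusters are reseeded with the worst-fit point. Classes are
canonicalized by descending size (ties by the first score coordinate),
since cluster numbering is otherwise arbitrary. k is fixed at 3
(intact-carbohydrate-rich, transitional, degraded); automatic model
selection is a non-goal. Whether correlation should operate on 4-D
score vectors or full spectra is ambiguous in the field literature;
the default operates on score vectors, with a spectra-space option
left untested against reference results.

# The phantom generator

Synthetic data must make every stage falsifiable, so the generator
mirrors the acquisition geometry and chemistry rather than the
radiative physics:

* **Tissues.** Vertical earlywood/latewood stripes with period
  `ring_period` (earlywood fraction 0.6) emulate 6–7 annual rings per
  sample without ring curvature; a configurable border of near-zero
  reflectance exercises background masking.
* **Chemistry.** Each wood pixel's absorbance is a convex mixture
  `A = c·S_carb + (1 − c)·S_lig` of two pure-component spectra built
  as Gaussian bands (the simplest smooth unimodal line shape —
  adequate for testing linear methods since band shape is not
  identified by any of them) at the carbohydrate and lignin band
  positions listed above, on a gently rising baseline. Decay at
  fraction `d` sets `c = c_0 (1 − d)` with `c_0 = 0.65`, so
  carbohydrate signal falls and lignin signal rises with decay — the
  brown-rot direction. Earlywood decays at least as fast as latewood
  at every position, and an optional baseline tissue-composition
  offset (default 0) can emulate the lower carbohydrate content of
  sound earlywood.
* **Acquisition.** Reflectance `10^{-A}` receives per-pixel
  multiplicative scatter (gain SD 0.05, offset SD 0.01), is encoded to
  counts against dark (1,500 counts) and white (52,000 counts × a
  smooth lamp spectrum) line-scan frames, and receives additive
  Gaussian detector noise (SD 30 counts) with clipping at the 16-bit
  full scale. With noise and scatter at zero, calibration followed by
  absorbance conversion inverts the generator to < 1e-6 — a round-trip
  identity the tests enforce.
* **Stacked experiment.** For ASCA testing, the generator emits
  average spectra directly on the SNV scale as a sum of pieces lying
  exactly in the factorial subspaces (position profiles from the decay
  schedule, a loading-shaped fungus contrast, a rank-one
  position × fungus pattern, centered per-replicate offsets, iid
  noise). Because each piece is stored, planted sums of squares are
  known exactly, and `target_fractions` rescales them to hit stated
  percentages — the default targets (position 75.7%, fungus 4.3%,
  position × fungus 8.1%, replicate 1.3%, noise 10.6%) reproduce the
  variation structure of a real stacked brown-rot decay test dominated
  by the position gradient.

What the phantoms deliberately lack: Kubelka–Munk/radiative scattering
physics, hyphal growth patterns, moisture effects, ring curvature, and
instrument wavelength miscalibration. Passing tests therefore
demonstrate algorithmic correctness and recovery under the stated
noise model, not robustness to every artifact of real acquisitions.

# Numerical choices and problem sizes

* Degenerate inputs are explicit: zero-variance spectra are flagged
  invalid rather than divided by ~0 in SNV; zero effect matrices are
  skipped in the per-effect SVD; empty classes warn and yield `NA`
  rows; empty masks, out-of-bounds ROIs and unbalanced designs error.
* Robust location/scale for thresholds is median/MAD (scaled), so a
  minority of extreme pixels cannot drag the threshold.
* Phantom images default to tens-of-pixels-squared geometry
  (e.g. 72 × 72 × 96 in the pipeline defaults, 140 × 120 × 288 for
  standalone cubes) rather than the full 1,029 × 384 × 288 camera
  frame; the spatial statistics exercised by the pipeline do not
  depend on pixel count, and these sizes keep a full synthetic run in
  seconds. The test suite runs its recovery experiments at 70 samples
  × 50–288 bands (ASCA), 500–5,000 pixels (PCA/outliers) and
  150–600 points (clustering).
* One integer seed drives every stochastic stage; reruns with the same
  configuration are bit-identical for deterministic artifacts.

# Known limitations

Only balanced full factorials are decomposed; mass loss enters as an
annotation, never a response; no spatial regularization or smoothing
beyond the initial median filter; correlation-metric k-means has no
closed-form objective guarantee (the Euclidean mode does, and is the
verified reference); and the phantom chemistry is a two-component
linear mixture, so nonlinear band interactions present in real wood
spectra are outside the model.
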