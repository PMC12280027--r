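---
title: "Quantitative islet morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative islet morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletmorph)
```

## The measurement problem

Pancreatic islets are micro-organs scattered through exocrine tissue. In
multichannel immunofluorescence sections, glucagon marks α cells, insulin
marks β cells, and pixels positive for both hormones define a *bihormonal*
compartment of possible transdifferentiation intermediates. Morphometric
questions — does islet area expand during pregnancy, do α cells contribute
more than β cells, is the change driven by cell number or cell size — reduce
to calibrated areas, counts and intensities extracted reproducibly from whole
sections. `isletmorph` implements that extraction, the associated two-group
statistics, Manders colocalisation, and an S0-moderated permutation FDR test
for companion proteomics matrices, together with a synthetic-section
generator that provides exact ground truth for validation.

## Segmentation model

The pipeline follows a fixed operator sequence per section:

1. **Tissue footprint.** The sum projection over all channels is thresholded
   and hole-filled. The Otsu threshold is computed on the `log1p`-transformed
   projection: on the linear scale a sparse, very bright hormone class can
   dominate the between-class variance and the "tissue" class collapses onto
   the islets; the log transform restores the slide-vs-tissue contrast as the
   dominant mode. The log transform affects only this projection threshold.
2. **Hormone channels.** Grayscale closing with a disc (default radius
   1.3 µm ≈ 2 px at the default 0.65 µm/px calibration) removes small dark
   gaps; a disc mean filter (same default radius) suppresses noise. Each
   channel is then thresholded with Otsu computed *within the tissue mask*,
   so that empty slide does not populate the background class. The threshold
   applies strictly (`intensity > t`).
3. **Whole islets.** The union of the two hormone masks is closed (default
   disc radius 3 µm, refining islet outlines and bridging interior gaps),
   labelled with 8-connectivity, and size-filtered: components with area
   < 1000 µm² are removed (retain means area ≥ 1000 µm²). `EBImage::bwlabel`
   is 4-connected; diagonal adjacencies are merged with a union-find over
   label ids to obtain 8-connectivity.
4. **Compartments.** Within the islet footprint, bihormonal = glucagon ∩
   insulin, α-only = glucagon \ insulin, β-only = insulin \ glucagon. Pixels
   of the footprint carrying neither mask (interior gaps filled by the islet
   closing) are assigned to the nearest hormone-positive class by distance
   transform, with a deterministic tie order (α, β, bihormonal). As a result
   **the three compartments partition the islet footprint exactly, for every
   input** — the property the per-islet proportions rely on. Exocrine tissue
   is the tissue mask minus the islet footprint.

Thresholds are computed per section rather than globally across a cohort
(either convention is defensible; per-section is the more robust default for
sections stained in separate batches); every threshold actually applied is
recorded in the run report.

## Nuclei

Nucleus counting uses the classical distance-transform watershed: Otsu
foreground on the (lightly smoothed) DAPI channel, Euclidean distance map,
watershed with tolerance `h` (the h-maxima depth, default 1 px). Objects
with equivalent diameter `2*sqrt(area/pi)` strictly greater than 10 µm are
discarded as artefacts or clumps; "larger than 10 µm" is read as a length,
hence a diameter criterion. Each nucleus is assigned to the compartment
containing its centroid — cheap, deterministic and order-independent;
centroids outside tissue are flagged and assigned to exocrine.

## Metrics

All areas are pixel counts × `pixel_size²`. Key derived quantities:

* **Fractional area** (% of a reference area). The reference is configurable:
  total tissue area (default, used for the headline comparisons) or exocrine
  area — both conventions appear in practice and the package supports either.
* **Mean area per islet** = total compartment area / islet count (missing
  when no islets survive the size filter).
* **Islet density** = islets per mm² of tissue.
* **Islet diameter** = maximum Feret diameter: the largest pairwise distance
  between boundary pixel centres, computed on the convex hull. A single-pixel
  object has diameter 0 by convention.
* **Estimated cell size** = compartment area / nuclei assigned to it;
  normalised nuclei counts are percentages of total islet nuclei.
* **Marker metrics** (e.g. GLP-1): the marker channel is mean-filtered (no
  closing) and thresholded within tissue; positive areas are reported within
  islet and α compartments, and intensity is the summed raw marker intensity
  over a compartment divided by the compartment area in mm² (AU/mm²) — the
  only reading consistent with that unit.

Percent quantities are scale-free: doubling `pixel_size` quadruples areas,
doubles diameters and leaves every percentage unchanged (tested).

## Colocalisation

Manders coefficients use the intensity-weighted thresholded definition:
with suprathreshold masks `A⁺`, `B⁺`,
`M1 = Σ_{A⁺∩B⁺} A / Σ_{A⁺} A`, and `M2` symmetrically. Thresholds gate the
masks only; no background is subtracted from the summed intensities. Default
thresholds are per-channel Otsu, with fixed overrides honoured verbatim. A
coefficient is reported missing when its channel has no suprathreshold
signal rather than silently zero.

## Two-group statistics

`compare_groups()` mirrors small-cohort practice: Shapiro–Wilk on each group
at α = 0.05; both compatible with normality → two-sided pooled-variance
Student t; otherwise two-sided Mann-Whitney (exact for small samples without
ties, midrank normal approximation under ties). Groups smaller than 3 cannot
be normality-tested and route to Mann-Whitney. No multiplicity correction is
applied across morphometric metrics; significance is declared at p < 0.05.

`ttest_from_summary()` recomputes a two-sided test from printed
mean ± SEM ± n: `t = (m₁ − m₂)/√(sem₁² + sem₂²)`, `df = n₁ + n₂ − 2` — the
pooled-variance test when group sizes are equal. This reconstruction
reproduces the published morphometry p-values (0.0145, 0.0058, 0.0027, …)
at their printed precision, which is also the evidence that the reference
workflow used the pooled rather than the Welch form; the handful of printed
p-values it does not reproduce are evidently those tested with Mann-Whitney
instead. Categorical donor characteristics use the two-sided Fisher
exact test (sum of hypergeometric probabilities not exceeding the observed
table's).

## Differential protein abundance

Matrices are log2-transformed and filtered to strict per-group completeness
(a protein with any missing value in either compared group is dropped — no
imputation). The moderated statistic is SAM-style:
`d = (mean_a − mean_b) / (s + s0)` with `s` the pooled two-sample standard
error and `s0 = 0.01` by default; the constant damps low-variance proteins
whose ordinary t would explode. With `s0 = 0`, `d` is exactly the pooled t
statistic (tested against the textbook formula).

The FDR is permutation-based: group labels are reassigned (all distinct
assignments when fewer than requested exist, otherwise a seeded subsample of
250 without replacement), giving a null set of statistics per permutation.
For each protein, the raw q is the median across permutations of the number
of null |d*| at least as large as the protein's |d|, divided by the number
of observed |d| at least that large, clipped to [0,1]. The q-curve is then
monotonised along the |d| ranking (each threshold receives the smallest q
achievable at or beyond it), so q is non-increasing in |d|. Discoveries are
declared at q < 0.05, i.e. −log10 FDR > 1.3, with the boundary case
classified non-significant (strict inequality). The estimator is validated
by simulation — null matrices yield ~0 discoveries, 50 proteins spiked at
log2FC = 2 with within-group SD 0.3 are recovered at ≥ 90% sensitivity with
≤ 1% null leakage — rather than by claiming bit-compatibility with any
specific proteomics platform, whose exact permutation scheme is not public.

## The synthetic-section generator

The generator is first-class, tested code: it renders what the segmentation
consumes and returns exact ground truth from the noise-free render.

* **Geometry.** Tissue is an ellipse (semi-axes 0.46/0.44 of the canvas,
  scaled by `tissue_scale` to emulate donor anatomy). Each islet is a
  lobulated union of a main disc (radius drawn from
  `islet_radius_range`) and three half-radius satellites; islets are placed
  by rejection sampling, non-overlapping and at least two islet radii apart,
  with an explicit error when the packing is impossible.
* **Territories.** Every islet is tiled exactly into β-core, bihormonal and
  α territories: pixel counts are fixed from the fractions, the α and
  bihormonal territories are carved as adjacent angular blocks from a
  peripheral band several times their joint area (keeping the blocks thick
  relative to the filter scale), and β takes the remainder. α placement is
  peripheral for visual realism only; all truth is mask-derived. The marker
  territory is a sub-arc of α covering `marker_positive_fraction_of_alpha`.
* **Nuclei.** Per-territory counts are `density × area/1000 µm²`; centres
  are blue-noise sampled with minimum separation `2r + 1.5 px` and kept one
  nucleus radius inside their territory (a nucleus disc belongs to a cell of
  that territory). Ground truth stores the placed centres, so truth and
  render agree even when dense packing truncates a count.
* **Intensities.** Channels are background (15 AU in tissue) plus signal
  (400 AU) on positive territory, a smooth sinusoidal background field
  (4 AU) and additive Gaussian noise (SD 8 AU), clamped at zero. The
  signal-to-noise ratio was chosen so that the default pipeline recovers
  noise-free truth within 5% — the generator emulates the *statistical*
  structure of micrographs (sparse bright classes over autofluorescent
  background), not optics: there is no PSF, no chromatic shift, no staining
  chemistry, no 3-D structure. Passing tests therefore validate the
  pipeline's operator logic and calibration handling, not its robustness to
  every real-world artefact.

Default control-section parameters (3000 × 3000 px at 0.65 µm/px, 6 islets
of 32–47 µm radius, α/β/bihormonal fractions 0.06/0.92/0.02) give a
whole-islet fractional area near 1.6% of tissue and mean islet area near
6250 µm², matching a non-pregnant human donor; α at ~6% of islet area and
the marker at ~22% of α match the control proportions.

### Cohort effects

`generate_cohort()` draws control donors (multipliers 1) and "pregnant"
donors whose generating parameters are scaled by per-metric multipliers
(defaults 1.9× islet, 4.3× α, 1.9× β, 5.4× bihormonal area, 2.39× marker
share of α, 1.33× marker intensity). Compartment multipliers act on the
territory fractions relative to the islet multiplier and the islet blob
absorbs their sum, so every *compartment* fold is exact by construction.
Because the compartments tile the islet, the realized whole-islet fold is
then the area-weighted mean of the compartment folds (~2.11× under the
defaults) rather than the nominal 1.9× — the same internal tension present
in the published numbers, where whole-islet area includes closing-filled
interior not attributed to any compartment. When all multipliers are equal
the islet fold is exact. Between-donor variability is lognormal with mean 1:
CV 0.25 on islet size, half that on territory and marker fractions, and a
6% CV on tissue size (which makes islet *density* properly exchangeable
between groups, as observed in the real cohort). Each donor section runs on
its own RNG stream seeded from (cohort seed, donor index).

### Protein matrices

`generate_protein_matrix()` draws per-protein baselines N(23, 2²) on the
log2 scale, replicate noise with within-group SD 0.3 (the `within_sd`
parameter exists because a spiked matrix is unrepresentable without a
replicate-noise scale separate from the between-protein spread), shifts the
first `n_true_effects` proteins by `effect_size` in group A, and censors
entries completely at random at `missing_rate`.

## Numerical conventions

* Otsu: exhaustive search over 256 histogram cut points between the observed
  minimum and maximum, maximising between-class variance; smallest
  maximising cut on ties; constant rasters warn and return an empty mask.
* Masks are half-open pixel grids on the image lattice, row-major, origin
  top-left; connectivity is 8-way for components.
* The `< 1000 µm²` islet size filter removes strictly smaller components.
* Degenerate denominators (no islets, no nuclei, zero total signal) yield
  missing values, never 0 or Inf; zero-variance two-group comparisons return
  p = 1; two equal-mean groups with zero SEM give p = 1, unequal means with
  zero SEM give the degenerate p = 0 with a warning.
* All simulation entry points take explicit integer seeds and restore the
  caller's RNG state.

## Problem sizes used by the test-suite and acceptance script

Validation balances fidelity against runtime; the sizes are choices of the
package, stated here for reproducibility. Ground-truth recovery runs three
noise-free 900 × 900 px sections at 1 µm/px with 4 islets. The partition
invariant runs 100 randomised 200 × 200 px sections at 2 µm/px including
noisy, empty and single-islet cases. Cohort power runs 100 replicate 7 + 7
cohorts of 320 × 320 px sections at 2.2 µm/px with 3 islets of 20–30 µm
radius; at this coarser scale thin-α attenuation inflates the measured folds
slightly, which is immaterial for a detection-rate check. Null calibration
runs 200 truth-level cohorts. FDR calibration uses 1000-protein, 6 + 6
matrices over 20 seeds with 250 permutations.

## Known limitations

* 2-D sections only; no stereological correction toward 3-D mass.
* Per-section Otsu thresholds can drift on sections whose positive fraction
  approaches zero; fixed thresholds are available and recorded.
* The Mann-Whitney route with heavy ties falls back to the normal
  approximation; exact p-values are only guaranteed for small untied
  samples.
* The permutation FDR with very small groups (< ~4 per group) has few
  distinct label assignments; the implementation then uses all of them and
  says so, but resolution is limited.
* The generator does not emulate section-to-section staining variability,
  tiling seams, or spatial correlation between nuclei and hormone intensity.
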