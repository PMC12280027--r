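# isletmorph

Quantitative morphometry of pancreatic islets in multichannel
immunofluorescence sections, with the statistics used to compare donor
groups and an S0-moderated permutation-FDR test for companion label-free
proteomics.

Islets are identified from glucagon (α-cell) and insulin (β-cell)
immunofluorescence: each channel is closed, mean-filtered and
Otsu-thresholded; the union of the hormone masks is closed, labelled with
8-connectivity and size-filtered (whole islets < 1000 µm² removed); the
footprint is then partitioned exactly into α-only, β-only and bihormonal
(glucagon ∩ insulin) compartments, with exocrine tissue as the thresholded
section minus the islets. Nuclei are counted by a distance-transform
watershed on the DAPI channel with a 10 µm equivalent-diameter artefact
filter and assigned to compartments by centroid. Per-section metrics follow
the field's definitions:

- fractional area `100·A_c / A_ref` (reference: tissue or exocrine area),
- mean area per islet `A_c / K`, islet density `K / A_tissue(mm²)`,
- islet diameter = maximum Feret diameter (longest axis),
- estimated cell size `A_c / nuclei_c`, normalised nuclei counts,
- marker (e.g. GLP-1) positive area per compartment and intensity in AU/mm²,
- Manders coefficients `M1 = Σ_{A⁺∩B⁺}A / Σ_{A⁺}A` (intensity-weighted,
  thresholded) for receptor/hormone overlap.

Group comparisons use a Shapiro–Wilk-gated two-sided pooled t /
Mann-Whitney test, Fisher's exact test for categorical donor tables, and a
summary-statistics t-test `t = (m₁−m₂)/√(sem₁²+sem₂²)`, `df = n₁+n₂−2`
that reproduces published p-values from printed mean ± SEM. Differential
protein abundance uses the SAM-style moderated statistic
`d = Δmean/(s + s0)` with permutation-based FDR (median false-positive
count over label permutations, monotonised along the |d| ranking).

A synthetic-section generator renders lobulated islets with α/β/bihormonal
territories, nuclei and a marker channel over an autofluorescent tissue
ellipse — with exact pixel-level ground truth — so every stage is testable
without any imaging data; a cohort generator applies the pregnancy effect
multipliers (1.9× islet, 4.3× α, 1.9× β, 5.4× bihormonal area) with
between-donor variability, and a matrix generator produces spiked
log-normal proteomics matrices with missingness.

## Worked example

```r
library(isletmorph)

p <- section_params(width = 900, height = 900, pixel_size = 1, n_islets = 4,
                    islet_radius_range = c(32, 47), seed = 7)
gs  <- generate_section(p)           # $section (4 channels) + $truth
cfg <- default_config(); cfg$pixel_size <- 1
res <- analyze_section(gs$section, cfg)
res$compartments
#> CompartmentSet: 4 islet(s); areas (um^2): islet 19297, alpha-only 1145,
#>   beta-only 17761, bihormonal 391, tissue 554660
```

The one-row `res$metrics` table carries every per-section quantity:

```
islet fractional area: 3.48% | mean islet area: 4824 um^2 | density: 7.21 /mm^2
alpha % of islet: 5.93 | beta: 92.04 | bihormonal: 2.03
islet nuclei: 154 | est beta cell size: 125.1 um^2 | GLP-1 % of alpha: 22.2
```

The four islets occupy 3.5% of the tissue section; α cells hold ~6% of the
islet area and the bihormonal compartment ~2%, matching the generator's
ground truth (`gs$truth$areas`) within a few percent. The β-cell size
estimate (125 µm² per nucleus) recovers the generator's territory-per-cell
value (1000/8 µm²).

Reconstructing a published comparison from printed summaries
(mean ± SEM, n = 7 per group):

```r
ttest_from_summary(3, 0.46, 7, 1.6, 0.16, 7)
#> t = 2.875, df = 12, p = 0.0140
```

A cohort runs end to end with
`run_full_pipeline(generate_cohort(cohort_params(), section_params()),
cfg, out_dir = "out")`, writing `metrics.csv` (one row per donor),
`comparisons.csv` (test, statistic, p per metric) and a JSON run report
with every parameter and threshold used.

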