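# behavex

Behavioral transcriptomics of regenerating airway epithelium: an R toolkit
that links what cells *do* in live-imaged tissue to what they *express* in
single-cell RNA-seq.

After airway injury, regenerating epithelial regions split into fast,
directionally migrating patches ("movers", mean speed > 4 µm/hr) and patches
that oscillate in place ("non-movers", < 1.5 µm/hr). `behavex` implements
the full analysis chain used to discover and characterise these states:

**Imaging arm**

- *Surface flattening.* Curved stacks are levelled by estimating the
  basement-membrane height per (x, y) from the collagen second-harmonic
  (SHG) channel — Gaussian blur (σ 10–25 µm in xy, 1–4 µm in z), then
  argmax over z — and subtracting it.
- *Tissue motion by PIV.* Multi-pass FFT cross-correlation (24, 16, 10 µm
  windows) yields displacement vectors **u**(x, y) on a 10 µm grid. Region
  speed is |**u**|/Δt in µm/hr; directionality is the circular variance
  1 − |⟨**u**/|**u**|⟩|; regions classify as mover / intermediate /
  non-mover by the strict thresholds above.
- *Division geometry.* For each division in a nucleus-track table, the
  angle between the daughter-separation axis and (i) the mother's
  interphase long axis, (ii) her preceding movement direction — the test of
  Hertwig's rule in regenerating tissue.
- *Ciliary beating.* Per-pixel beat frequency from 150 Hz surface movies by
  Welch power spectral density (Hann windows, 50 % overlap), and
  mucociliary transport speed from bead tracks.

**Transcriptomic arm**

- QC (1 000 ≤ genes detected ≤ 10 000, ≥ 25 % reads mapped), variable-gene
  selection by binomial deviance of the detection fraction against gene
  abundance (residual < −0.15), PCA on log₂ values, Ward.D2 hierarchical
  clustering on 1 − Pearson distance over epithelial marker genes with
  basal/club/low-quality identity calls.
- *Hurdle differential expression* between mover and non-mover basal cells:
  per gene, a logistic detection component and a Gaussian component on
  log₂(TPM+1) over expressing cells, both with cellular detection rate and
  mouse as covariates; the group term is tested by a summed likelihood-ratio
  statistic (χ², df = number of estimable components) with
  Benjamini–Hochberg FDR.
- *Signature scoring* of any cell against a gene set: mean log₂ expression
  of the n signature genes minus the mean of 10 n background genes matched
  per-gene in (mean expression, detection frequency) space — so coverage
  and library complexity cancel. Group contrasts use Mann-Whitney U tests.
- *SNN clustering* for droplet-style re-analysis: vst-type variable genes,
  PCA (25 PCs), shared-nearest-neighbor graph with Jaccard edge weights,
  Louvain modularity at resolution 0.25.

A first-class synthetic-data module (`simulate_tissue_movie()`,
`simulate_cilia_movie()`, `simulate_counts()` plus the `plate_scenario()` /
`injury_scenario()` study presets) generates every input with planted
ground truth, so the whole chain is testable without any external data.

## Worked example

The end-to-end pipeline — simulate a two-speed movie, run PIV, classify
regions, simulate matched plate-based counts, QC, cluster, hurdle DE,
derive mover/non-mover signatures, score an injury time course, SNN-cluster
the 24 h cells — runs from one config:

```r
library(behavex)
run <- run_pipeline(default_config(seed = 1))
run
#> <pipeline_run>
#>   mover regions: 30 / 81 grid vectors
#>   DE genes (FDR < 0.05): 30 mover, 32 non-mover
#>   planted-set recovery: precision 0.97, recall 0.97
```

30 of 81 grid regions exceed 4 µm/hr (the planted fast half of the movie),
the hurdle model recovers 30 mover and 32 non-mover genes at FDR < 0.05,
and 97 % of the reported mover genes are truly planted. Scoring the injury
time course with the recovered mover signature reproduces the expected
dynamics — strong enrichment at 24 h that resolves by one week:

```r
run$timepoint_tests
#> # A tibble: 4 × 7
#>   group reference     n n_ref     U        p median_diff
#>   <chr> <chr>     <int> <int> <dbl>    <dbl>       <dbl>
#> 1 168   uninjured   150   150 11031 7.71e- 1    -0.00565
#> 2 24    uninjured   600   150 21214 1.22e-23     0.558
#> 3 48    uninjured   150   150  1026 3.56e-42     0.439
#> 4 72    uninjured   150   150  3079 1.50e-27     0.257
```

Each `p` is a two-sided Mann-Whitney test of that timepoint's mover-score
distribution against uninjured cells; `median_diff` is the score shift.
Individual stages are ordinary piped functions, e.g.

```r
piv_movie(stack, "nuclear") |>
  region_speeds() |>
  dplyr::mutate(class = classify_region(speed_um_hr)) |>
  plot_speed_distribution()
```

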