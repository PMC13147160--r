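# coldmotility

Quantitative analysis of how cold exposure and cold acclimation reshape
T-cell behavior, built for time-lapse imaging data where cells are
represented as binary masks. Cultured T cells crawl vigorously at 37 °C
but round up and stop below ~32 °C; cells pre-incubated for ~24 h at a
subphysiological temperature ("cold-acclimated") regain motility in the
cold, alongside a large increase in mitochondrial spare respiratory
capacity and broad transcriptional remodeling. This package implements
the complete quantitative pipeline for that kind of study — motility and
morphology metrics from mask movies, cohort statistics, extracellular-flux
parameter derivation, and differential-expression summaries — together
with a ground-truthed synthetic amoeboid-cell generator so every stage can
be exercised and validated end to end without raw recordings.

It is intended for cell biologists and image analysts quantifying
temperature (or drug/genotype) effects on amoeboid cell motility from
segmented time-lapse data.

## What it computes

For each tracked cell, from binary masks `C_t` at 3-min intervals
(frames 0, 9, 18, … of a 20-s, 60-frame recording):

- **Cell deformation area** — the area newly occupied over the interval,
  `A_CD = Area(C_{t+3min} \ C_t)`, evaluated on superimposed masks. In
  purely translational movement area gained equals area lost; asymmetry
  reflects spreading or contraction.
- **Centroid displacement** — Euclidean distance moved by the mask
  centroid over the interval.
- **Circularity index** — `perimeter² / (4π · area)`: 1 for a circle,
  larger for irregular contours. The perimeter comes from a smoothed
  subpixel boundary contour, chosen so a rasterized disk scores ≈ 1
  rather than the large positive bias of boundary-pixel counting.

Cells qualify only if they are present in every frame, never touch the
field border, and never come within 2 px of another cell. Cohorts are
compared with Welch's t-test (two-sided, Welch–Satterthwaite df), the
usual star labels (`*` p < 0.05 … `****` p < 0.0001), and fold changes of
group means.

From phase-labeled OCR traces (basal → oligomycin → FCCP →
rotenone/antimycin A), the standard mito-stress-test parameters are
derived per well and normalized to protein: basal respiration, ATP-linked
respiration, proton leak, maximal respiration and spare respiratory
capacity (maximal − basal), with the identity
`ATP-linked + proton leak = basal respiration` holding exactly.

From per-gene statistics tables, genes are classified with the standard
rules (|log2FC| ≥ 1, Benjamini–Hochberg FDR < 0.05), summarized as counts
and percentages of detected genes, and prepared for volcano plots and
row-Z-scored heatmaps (clamped to ±2).

## Worked example

Simulate a cold-imaged cohort without and with acclimation (programmed
8-fold speed contrast, 0.2 vs 1.6 µm/min, and stronger membrane
protrusion), run the full mask pipeline, and compare:

```r
library(coldmotility)
conds <- list(
  cold_nonAC = list(n_cells = 5, mean_speed_um_per_min = 0.2,
                    persistence = 0.5, protrusion_amplitude = 0.1,
                    field_size_px = c(420L, 420L)),
  cold_AC    = list(n_cells = 5, mean_speed_um_per_min = 1.6,
                    persistence = 0.5, protrusion_amplitude = 0.4,
                    field_size_px = c(420L, 420L)))
res <- run_motility_pipeline(conds, seed = 26L,
                             comparisons = list(c("cold_nonAC", "cold_AC")))
res$comparisons[, c("metric", "mean_ref", "mean_test", "p_value",
                    "stars", "fold_change")]
#>                 metric mean_ref mean_test  p_value stars fold_change
#> 1         mean_acd_um2    5.319     28.54 5.78e-05  ****        5.37
#> 2 mean_displacement_um    0.297      2.30 4.82e-05  ****        7.75
#> 3     mean_circularity    1.035      1.38 8.99e-06  ****        1.33
```

The acclimated cohort deforms more (mean A_CD 28.5 vs 5.3 µm² per 3-min
pair), travels farther (2.30 vs 0.30 µm per 3 min, a 7.8-fold change
against the programmed 8), and has a higher circularity index because its
contours are more protrusive — each per-cell value is the mean over the
recording's complete 3-min pairs.

## Analysis workflow

The `analysis/` scripts run the full synthetic study and write their
tables under `results/`:

1. `01_simulate_cohorts.R` — condition table (temperature sweep 26–37 °C,
   non-acclimated vs acclimated) and an example mask movie (TIFF + JSON
   sidecar, under `scratch/`).
2. `02_motility_analysis.R` — the motility pipeline over the sweep;
   per-cell tables, inclusion report, per-temperature Welch comparisons.
3. `03_flux_analysis.R` — mito-stress-test wells for both conditions;
   per-well parameters and the acclimation contrast on summary parameters.
4. `04_de_analysis.R` — differential-expression classification and
   summary at the 15,234-gene scale, volcano coordinates, Z-scored
   heatmap matrix (bulky per-gene tables go to `scratch/`).

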