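# gliamux

Single-cell phenotyping of microglia from multiplexed fluorescence
immunohistochemistry.

## What problem this solves

Neuropathology studies of ALS and related TDP-43 proteinopathies ask how
microglia change alongside pathology: does phagocytic CD68 rise with
phosphorylated-TDP-43 aggregate burden, do L-ferritin-high dysfunctional
states emerge, are these shifts tissue-wide or confined to subpopulations?
Multiplexed IHC answers this with aligned multi-channel images per tissue
section — five microglial functional markers (L-ferritin, HLA-DR, CD68,
CD74, Iba1) plus pathology channels (pTDP-43, GFAP) — but turning those
images into defensible per-cell and per-case statistics takes a pipeline:
segmentation, per-cell measurement, gating, clustering and multiplicity-
controlled inference. `gliamux` is that pipeline for R, aimed at
quantitative neuropathology groups working with mask-based histocytometry
on small human cohorts (≈10 cases per group) or longitudinal mouse models.

## The method in brief

1. **Cell identification.** Per-marker binary masks (fixed "clip" or
   local-mean adaptive thresholds) are unioned into a *master mask*
   (Iba1 ∪ HLA-DR ∪ CD68 ∪ CD74; L-ferritin is excluded because astrocytes
   co-express it). Each 8-connected component within the ROI is one cell;
   the mean intensity of each marker over a cell's pixels estimates its
   per-cell protein concentration.
2. **Tissue-wide measures.** pTDP-43 load = Σ intensity inside its
   high-immunoreactivity mask / ROI area (after zeroing pixels under a
   high-HLA-DR mask to remove inter-round bleed-through); GFAP load = mask
   area / ROI area; microglial density = cells/mm²; tissue-wide marker
   intensity = Σ intensity over the master mask / ROI area.
3. **Gating.** Each cell is MOI^high or MOI^low per marker: cutoffs fitted
   on cells pooled across all cases (valley of the log-intensity density
   between its two major modes, with a quantile fallback) or set manually;
   classification is strict (> cutoff). Per-case %MOI^high is the key
   endpoint.
4. **Clustering.** Balanced subsampling per (group × region), natural-log
   features, Barnes–Hut t-SNE (learning rate N/12, early exaggeration 12
   for 250 of 1000 iterations, perplexity 250), kNN graph with k = ⌊√N⌋,
   Louvain communities. Cluster phenotypes are read from the *relative*
   MOI^high percentage — cluster minus case overall, in percentage points,
   so 0 means "mirrors the case" and the cell-share-weighted mean is
   exactly 0.
5. **Statistics.** Mann–Whitney per endpoint (exact enumeration for
   combined n ≤ 16 without ties), families controlled by the two-stage
   Benjamini–Krieger–Yekutieli step-up at FDR 0.01; Spearman correlation
   matrices with |r| > 0.7 flagged very strong (pTDP-43 suppressed in
   control groups, which carry no aggregates); and a
   genotype × timepoint two-way ANOVA (Type III) with per-timepoint
   Bonferroni contrasts for longitudinal mouse designs.

A ground-truthed simulator (`simulation_config()`,
`generate_cell_table()`, `generate_image_set()`) renders multi-channel
tissue fields — non-overlapping somata with phenotype-specific log-normal
intensities, astrocytes in GFAP/L-ferritin only, bright pTDP-43 aggregate
blobs whose per-case burden is co-planted with the CD68-high fraction,
Gaussian noise, optional HLA-DR→pTDP-43 bleed — so every stage above is
validated against planted truth. See the methods vignette
(`vignettes/microglial-phenotyping.Rmd`) for the model, parameter
defaults, and design rationale.

## Worked example

Simulate a small two-group cohort of tissue fields, quantify, gate, and
compare groups:

```r
library(gliamux)

cfg <- simulation_config(
  groups = data.frame(group = c("control", "disease"),
                      region = "motor_cortex", n_cases = 4),
  cells_per_case = 40,
  image_params = list(width_px = 256, height_px = 256, um_per_px = 1,
                      n_astrocytes = 4, aggregate_count_per_case = 40),
  seed = 42)
sim <- generate_image_set(cfg)

clips <- c(iba1 = 40, hladr = 40, cd68 = 40, cd74 = 40,
           ptdp43 = 200, gfap = 100)
quants <- lapply(sim$images, quantify_image_set, clip_thresholds = clips)
loads <- do.call(rbind, lapply(quants, `[[`, "loads"))
loads[, c("case_id", "group", "cell_density", "ptdp_load")]
#>                  case_id   group cell_density ptdp_load
#>  control_motor_cortex_01 control          694       0.0
#>  ...
#>  disease_motor_cortex_01 disease          694      19.7
#>  disease_motor_cortex_02 disease          694      15.5
#>  disease_motor_cortex_03 disease          694      36.1
#>  disease_motor_cortex_04 disease          694      23.4
```

All 40 planted somata per field are recovered (694 cells/mm² in these
0.058 mm² ROIs), control fields show zero pTDP-43 load, and disease loads
vary with each case's planted severity. Gating and group comparison:

```r
cells <- do.call(rbind, lapply(quants, `[[`, "cells"))
thr <- fit_thresholds(cells, method = "valley")
thr$cd68
#> <moi_threshold> cutoff 138.3 (valley, fitted)

pct <- percent_high(classify_moi(cells, thr))
ep <- data.frame(case_id = pct$case_id, group = pct$group,
                 region = pct$region, endpoint = pct$marker,
                 value = pct$pct_high)
compare_groups(ep, q = 0.01)
#>        region  endpoint median_control median_disease   U      p q_flag stars
#>  motor_cortex      cd68          10.00           42.5 0.0 0.0286  FALSE     *
#>  motor_cortex      cd74          11.25           16.2 4.0 0.3065  FALSE    ns
#>  motor_cortex     hladr          11.25           16.2 4.0 0.3065  FALSE    ns
#>  motor_cortex      iba1          91.25           90.0 8.5 1.0000  FALSE    ns
#>  motor_cortex lferritin           3.75           23.8 0.0 0.0275  FALSE     *
```

The CD68 cutoff (138) falls in the valley between the planted low and
high modes (60 and 269). The disease group's %CD68^high median is 42.5%
versus 10% in controls — the planted mixture shift — with the smallest
possible exact Mann–Whitney p for 4 vs 4 (U = 0, p = 0.0286). That earns a
raw-p star but no FDR-0.01 discovery: with four cases per group the exact
test cannot reach q = 0.01, which is exactly why the full design uses ten
cases per group (at 10 vs 10 the same planted shift is flagged at FDR 0.01
in every simulated replicate).

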