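---
title: "Methods: multiplexed-IHC single-cell phenotyping of microglia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplexed-IHC single-cell phenotyping of microglia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliamux)
```

## The analysis problem

Multiplexed fluorescence immunohistochemistry of brain tissue yields, after
channel extraction and inter-round alignment, a stack of co-registered
single-channel images per section: five microglial functional markers
(L-ferritin, HLA-DR, CD68, CD74, Iba1), pathology markers (phosphorylated
TDP-43, GFAP), and anatomical counterstains. `gliamux` turns such a stack
into (i) tissue-wide measures of pathology burden and microglial marker
expression, (ii) a single-cell table of per-cell marker concentrations,
(iii) a binary high/low phenotype per cell and marker, (iv) phenotype
clusters from a t-SNE embedding with kNN–Louvain community detection, and
(v) the group-comparison and correlation statistics appropriate to small
human cohorts (about ten cases per group).

Everything below is exercised end to end on synthetic data with planted
ground truth, so each stage's accuracy is measured, not assumed.

## Image quantification

**ROI.** All measures are restricted to a analyst-supplied region of
interest (a logical mask) and normalised to its area; content outside the
ROI never contributes.

**Masks.** Two thresholding operators build binary masks:

* `clip_threshold_mask()` — pixels strictly above a fixed cutoff. Used for
  "high immunoreactivity" masks (pTDP-43 aggregates, GFAP, bleed-through
  removal). Cutoffs are per-channel configuration; there is deliberately no
  automatic default, because they depend on acquisition settings.
* `adaptive_threshold_mask()` — pixels above the local mean (square window,
  exact integral-image computation, border-normalised) plus an offset. The
  default window of 25 µm spans a microglial soma and its proximal domain;
  the offset is required configuration. This local operator tracks uneven
  illumination and background that defeat a single global cutoff.

`master_mask()` is the pixelwise union of per-marker masks. For human
tissue the union of Iba1, HLA-DR, CD68 and CD74 masks identifies all
microglia immunoreactive for any of the four; L-ferritin is excluded
because astrocytes co-express it. For mouse tissue an Iba1 mask alone
suffices (all mouse microglia are strongly Iba1-positive).

**Bleed-through.** Residual high HLA-DR signal from a previous labelling
round can cross into the pTDP-43 channel. `subtract_bleedthrough()` builds
a high-HLA-DR clip mask and zeroes those pTDP-43 pixels — a mask
subtraction, not an arithmetic one, so it cannot create negative
intensities and does not assume a linear bleed coefficient.

**Cells.** `label_objects()` takes the 8-connected components of the
master mask within the ROI as cells. Components below `min_area_px`
(default 20 px, about 5 µm² at 0.5 µm/px) are discarded as fragments.
Objects touching the ROI border are kept; with a documented convention
either choice is reproducible, and keeping them avoids a density bias for
small fields. Coordinates are 0-based `(row, col)`.
`measure_cells()` then averages each marker over each object's pixels —
with uniform labelling this approximates the protein concentration per
cell.

**Tissue-wide measures.** `pathology_load()` is integrated intensity in a
mask over ROI area (µm⁻²); `area_load()` is mask area over ROI area (the
GFAP astrogliosis measure); `cell_density()` is cells per mm²;
`tissue_wide_intensity()` is a marker's integrated intensity over the
master mask normalised, by default, to ROI area. A `normalise = "mask"`
variant divides by master-mask area instead; the two differ by the mask
area fraction and answer slightly different questions (tissue burden
versus per-microglial-area concentration), so both are exposed rather than
silently picking one.

## High/low gating

`fit_threshold()` supports three pathways. `valley` fits a kernel density
to pooled log-intensities, keeps modes at least 5% of the dominant mode's
height, and puts the cutoff at the density minimum between the two largest
modes; if fewer than two genuine modes exist, or the dip between them is
shallower than 10% of the lower mode, the input is treated as unimodal and
the method falls back — with a warning and recorded provenance — to an
upper-quantile cutoff (default 0.9). `quantile` and `manual` are direct.
In practice only Iba1 shows clean bimodality in human tissue; the other
markers' cutoffs are set manually from scatter structure, which the
`manual` pathway records with provenance.

Cutoffs are fitted on cells pooled across **all** cases, never per case or
per group: a per-group cutoff would build the group difference into the
gating. Classification is strictly greater-than (a cell exactly at the
cutoff is low) — an arbitrary but fixed convention, required for
reproducibility. `percent_high()` then reports the percentage of MOI-high
cells per case, region and marker.

## Embedding and clustering

`subsample_balanced()` draws the same number of cells from every
(group, region) subgroup so no subgroup dominates the embedding — at full
cohort scale, 31,200 per subgroup for a pool of 124,800. Features are the
natural logs of the five marker intensities (`log_transform()`; equal
weighting, no scaling, fixed column order). `tsne_embed()` wraps
Barnes–Hut t-SNE with the learning-rate rule eta = N/EE, where the
early-exaggeration factor EE = 12 is applied for the first 250 of 1000
iterations, and perplexity 250 (reduced with a warning to (N−1)/3 for
small runs). `knn_graph()` builds the unweighted, union-symmetrised
k-nearest-neighbour graph on the 2-D embedding with k = ⌊√N⌋, breaking
distance ties by index order (exact search up to N = 2000, kd-tree
beyond). `louvain_cluster()` maximises modularity; labels are contiguous
from 1 in decreasing size order and runs are deterministic given a seed.

**The resolution choice.** Modularity at resolution 1 on the kNN graph of
a continuous 2-D embedding subdivides each contiguous island of points
into patch-scale communities: on four well-separated planted phenotypes
(N = 4000) it returns 12–13 clusters with an adjusted Rand index of about
0.45 against the planted labels, and at full cohort scale this is the
regime in which dozens of clusters arise that are not spatially distinct
in the embedding. Any resolution between about 0.01 and 0.3 instead
returns exactly the phenotype islands (ARI ≈ 1.0). `louvain_cluster()`
therefore exposes `resolution` with default 1 (the classical objective,
matching igraph), and the package's phenotype-recovery validation runs at
0.1 — a value chosen for being in the middle of a thirty-fold stable
range, not at a threshold. Users probing for genuinely distinct
subpopulations should use a coarse resolution; users cataloguing subtle
expression shifts may prefer the fine default, understanding that those
clusters partition a continuum.

Clustering runs on the 2-D embedding by default (as a visualisation-first
histocytometry workflow does); `cluster_on = "features"` clusters the 5-D
log-feature space as a sensitivity analysis.

**Composition measures.** `cluster_group_contribution()` gives each
cluster's percentage split between groups (rows sum to 100; regions pooled
by default, with a per-region flag). `cluster_case_percentages()` gives
each case's distribution over clusters (sums to 100 per case).
`relative_moi_high()` phenotypes clusters: the percentage of MOI-high
cells among a case's cells in the cluster minus that case's overall
MOI-high percentage. The difference (rather than a ratio) makes zero the
natural baseline and gives the exact identity that the cell-share-weighted
mean over clusters is 0 for every case and marker — a conservation law the
tests assert to machine precision.

## Statistics

* `mann_whitney_u()` — exact enumeration of all group assignments for
  combined n ≤ 16 without ties (two-sided p as the probability of a U at
  least as extreme, by the symmetry of the null distribution); otherwise
  the normal approximation with tie and continuity correction. The
  exact/approximate switchover at 16 is a documented package convention.
* `bky_two_stage_adjust()` — the adaptive two-stage linear step-up at FDR
  q: stage 1 at q′ = q/(1+q); m₀ estimated as m − r₁; stage 2 at q′·m/m₀.
  Both stages use q′, following the published two-stage definition. Note
  the procedure is not uniformly more powerful than single-stage BH: in
  borderline families where stage 1 rejects nothing it makes no
  discoveries at all. Discovery flags are monotone in p within a family.
* `compare_groups()` — one Mann–Whitney per endpoint, FDR-controlled per
  region-family at q = 0.01, with group medians, the raw-p star labels
  (≤0.05 … ≤0.0001) and the FDR decision reported side by side, since a
  raw-p star and an FDR discovery are different statements.
* `spearman_matrix()` — tie-corrected Spearman with pairwise-complete
  cases, |r| > 0.7 flagged "very strong", constant variables returned NA
  with a warning, and a `suppress_vars` argument used to exclude pTDP-43
  from control-group matrices (control tissue carries no aggregates, so
  the correlation is undefined by design, not missing by accident).
* `two_way_anova_bonferroni()` — the longitudinal mouse arm:
  genotype × timepoint linear model with sum contrasts and Type-III sums
  of squares (unbalanced cells allowed), pooled-error genotype contrasts
  at each timepoint, raw p multiplied by the number of timepoints and
  capped at 1.

## The synthetic cohort

`simulation_config()` + `generate_cell_table()` / `generate_image_set()`
define the study conditions under which everything above is validated.

* **Phenotypes** are binary high/low profiles over the five markers, with
  named presets (homeostatic Iba1-only, pan-low, CD68-high,
  L-ferritin/CD68-high, L-ferritin-high/CD74-low, HLA-DR/CD74-high)
  mirroring recurring reactive-microglia profiles.
* **Intensities** are log-normal per (phenotype, marker): right-skewed,
  strictly positive, matching single-cell immunofluorescence density
  curves. Defaults put low and high modes 6 log-sd apart (meanlog log 60
  and log 60 + 1.5, sdlog 0.25), comfortably above the 4 log-sd separation
  the gating validation assumes. Absolute scales are arbitrary (no
  physical calibration exists) and fully config-exposed.
* **The disease effect is a mixture-fraction shift, not a mean shift**:
  disease motor cortex raises the CD68-linked phenotype fractions
  (8% → 43% CD68-high by default) while component means stay put — a
  tissue-wide intensity increase driven by *more high-expressing cells*.
  Disease hippocampus keeps control fractions.
* **Between-case variability** has two parts: a log-normal jitter of all
  fractions (sd 0.2) and, for disease cases, a latent severity multiplier
  (log-normal, sd 0.35) scaling the CD68-linked fractions. The same latent
  scales the expected pTDP-43 aggregate count (Poisson, 150 expected
  aggregates at a reference CD68-high fraction of 0.4 in a default-size
  field), so %CD68-high and aggregate load are co-planted across cases —
  the disease group's hallmark correlation — while control cases carry no
  aggregates at all.
* **Images** render somata as non-overlapping uniform disks (radius 5 µm,
  placed by rejection sampling with a minimum gap; placement fails loudly
  when requested somata would exceed half the ROI). Astrocytes appear only
  in GFAP and L-ferritin (the co-expression that forces L-ferritin out of
  the master mask), aggregates are small bright blobs, Gaussian background
  noise is added everywhere, and an optional bleed coefficient adds HLA-DR
  signal into the pTDP-43 channel to exercise the correction. Truth
  records every placement, planted intensity, per-case phenotype fraction,
  aggregate load and astrocyte coverage.

What the simulator does **not** emulate: point-spread optics, 3-D stacks,
microglial processes and morphology, inter-round misalignment, autofluorescence
gradients, or segmentation errors from touching cells. Passing the
recovery tests therefore demonstrates the pipeline's correctness on
cleanly separable somata, not robustness to real-tissue segmentation
ambiguity — those failure modes need real annotated tissue to assess.

## Validation scale and results

The test suite and `scripts/acceptance.R` run at desk scale: 256-px fields
at 1 µm/px with 40 somata per case (so tens of cases render in seconds),
4000-cell embeddings for clustering recovery, 1000 simulated families for
null calibration, 20 cohort replicates for power. These sizes were chosen
so the whole validation runs in minutes while every tolerance is still
binding: cell counts recover exactly; pTDP-43 and GFAP loads recover
within 5% (sub-0.1% observed without bleed, ~1% after bleed correction);
per-case MOI-high percentages recover within 5 points (≤ 2.5 observed);
phenotype-recovery ARI exceeds 0.8 (≈ 1.0 observed at resolution 0.1);
Mann–Whitney type-I error sits at 0.05 within Monte-Carlo tolerance; a
25-point CD68-high shift with 10 cases per group is discovered at FDR 0.01
in essentially every replicate; and the default disease cohort shows a
very strong (r > 0.7) CD68-high/pTDP-43-load Spearman correlation in the
disease motor cortex with the control correlation suppressed as undefined.

## Known limitations

* The MetaMorph-style "adaptive threshold" is reconstructed as a
  local-mean operator; the proprietary original is unspecified, so only
  qualitative agreement can be claimed.
* Manual scatter-plot thresholding is represented by the `manual` pathway
  plus provenance; the package does not reproduce an analyst's eye.
* t-SNE embeddings are seed-reproducible within one Rtsne build but not
  across implementations; cluster *identities* (which cells cluster
  together at coarse resolution) are far more stable than cluster numbers.
* Mann–Whitney p-values for n = 10 + 10 are discrete; exact calibration at
  α = 0.05 is approximate by nature.
* The per-case value of a multi-field section is an area-weighted mean
  across fields; the package treats one field per case in the simulator.
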