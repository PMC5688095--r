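---
title: "Quantifying PLA signal in imaging flow cytometry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PLA signal in imaging flow cytometry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plicr)
```

## The measurement problem

A proximity ligation assay (PLA) reports a protein–protein interaction or a
post-translational modification as a bright, compact fluorescent punctum: when
two antibody-coupled oligonucleotide probes come within a few tens of
nanometres, they template rolling circle amplification and the product is read
out as a localized dot. Read on an imaging flow cytometer (IFC), each cellular
event yields a small multichannel image — a brightfield view, the PLA channel,
and surface-marker stains — so rare, marker-defined subpopulations (the
motivating case is CD80-high medullary thymic epithelial cells, a few hundred
to a thousand events per sample) can be quantified cell by cell.

The quantity of interest is simple: **the percentage of PLA-positive cells in a
population**. The difficulty is that naive thresholding of PLA intensity counts
three artifact classes as positives:

* **membranal nonspecific binding** — probes stick to the cell surface and
  amplify there, producing bright puncta in a ring at the cell boundary;
* **autofluorescent cells** — a diffuse elevation across the whole cell,
  bright in total but without compact detail;
* **channel bleed-through** — fluorescence penetrating from an adjacent
  channel, which survives spillover compensation when it is strong.

`plicr` implements the image features, masks and the multi-stage gating
cascade that separate genuine nuclear-speckle signal from these artifacts,
the spillover compensation that precedes them, the replicate-level
statistics that turn per-cell calls into experiment-level comparisons, and a
synthetic image generator that plants all of the above with known ground
truth.

## Feature operators

All features are computed inside a **morphology mask** (every pixel within the
outermost image contour: Otsu threshold on the brightfield-proxy channel,
largest connected component, holes filled) or its **adaptive-erode** interior
(the mask iteratively eroded until just above a retained-area percentage,
78 by default — an erosion that follows the cell's own shape and strips the
membranal rim).

* **Bright Detail Intensity (BDI)** — the summed intensity of bright spots of
  radius ≤ 3 px: the white top-hat transform (image minus its morphological
  opening by a radius-3 disc), summed over the mask. Uniform staining and
  diffuse autofluorescence cancel; puncta survive.
* **Max Pixel** — the largest background-subtracted pixel in the mask. The
  background is the half-sample mode of the out-of-mask pixels: robust,
  parameter-free, and exactly shift/scale-equivariant, so BDI and Max Pixel
  inherit clean invariances (adding a constant changes nothing; scaling scales
  them).
* **Max Contour Position (MCP)** — the mask is partitioned into 8 concentric
  rings by normalized distance to the mask boundary; MCP is the midpoint
  position (0 = center, 1 = perimeter) of the ring with the highest mean
  intensity. Nuclear signal scores low; membranal signal scores near 1.
* **Staining area** — the number of mask pixels whose background-subtracted
  intensity exceeds half the cell's Max Pixel. Compact puncta give a few
  pixels; diffuse elevation lifts most of the cell past the cutoff and
  saturates the area.
* **Bright Detail Similarity (BDS)** — the Fisher z-transform,
  `0.5·log((1+r)/(1−r))`, of the Pearson correlation `r` between the
  bright-detail images of two channels, with `r` clipped to ±0.999 (capping
  BDS near 3.8). Genuine signal in one channel is uncorrelated with another
  channel's bright detail (BDS ≈ 0); bleed-through is nearly identical
  bright detail in both (BDS > 1.5 corresponds to r > 0.905).

**Where BDS is evaluated.** BDS is computed over the adaptive-erode interior
mask rather than the full morphology mask. The reason is geometric: the
rasterized boundary of any uniformly stained cell has single-pixel
protrusions at curvature extremes that a radius-3 opening cannot reconstruct,
so the top-hat of a marker channel acquires a handful of spurious
boundary-pixel spikes at roughly the staining amplitude. Those few pixels are
enough to decorrelate otherwise-identical interior speckle patterns (we
measured r ≈ 0.86 on noise-free copies) and would blunt the artifact filter.
The interior mask is where overlaid speckle artifacts live, and excluding the
rim restores r ≈ 0.98 for true copies while independent patterns stay near 0.

## The gating cascade

1. **Compensation** (optional, first): pixelwise linear unmixing against a
   spillover matrix estimated from single-stain controls — per-cell
   background-subtracted channel sums over the source-channel morphology mask,
   median of off/source ratios per row, diagonal fixed at 1. Unmixing happens
   before masking and features, and negatives are floored at zero.
2. **Population assignment** from background-subtracted total marker
   intensities: control-marker-high cells (CD45-like) form the control
   population; the rest split into target-high/low on the target marker
   (CD80-like) by a fixed, percentile, or 2-means cutoff.
3. **Raw PLA gate**: a cell is raw-positive iff its PLA-channel BDI *and* Max
   Pixel both exceed the 99.5th percentile (type-7 sample quantile) of the
   probes-only control — the sample carrying PLA probes but no primary
   antibody, which defines what "background" looks like.
4. **Localization filter** (full cascade only): BDI and Max Pixel recomputed
   on the adaptive-erode interior must still pass the same cuts (membranal
   rings fail), MCP must be ≤ 0.6 when the target is nuclear, and the PLA
   staining area must lie in [2 px, 40% of the mask] (diffuse cells fail the
   upper bound).
5. **BDS filter**: cells with BDS > 1.5 against the spectrally adjacent
   channel are excluded as bleed artifacts.

The final call is the conjunction of the raw gate and every enabled filter, so
the positive set is invariant to filter order; the recorded evaluation order
only organises the audit trail (each excluded cell lists every gate it
failed). The reduced cascade used for abundant populations (macrophage-style
analyses) applies the raw gate alone.

## Replicate structure and statistics

Each biological replicate (one animal) yields a percentage of PLA-positive
cells per population. Replicates are averaged — unweighted — within each
experimental group of each independent experiment, and the two groups are
compared with a two-sided, equal-variance (classical Student) two-sample
t-test on the experiment-level means, with the s.e.m. across experiments
reported alongside. Equal-variance is the default deliberately; Welch's test
sits behind a flag. Cell counts are reported but never used as weights: the
animal, not the cell, is the unit of replication, and the experiment, not the
animal, is the unit of inference. Two-sided testing is assumed throughout.
With zero variance in both groups the statistic is 0 (equal means) or signed
infinity (flagged); fewer than two experiments per group is refused rather
than silently tested.

## The synthetic-data generator

The generator emulates one-event-per-image IFC acquisition: a centred cell
disk on a fixed odd-sized grid (33 px default, cell radius 12, nucleus at
half the cell radius), four channels (brightfield proxy, PLA, a CD80-like
target marker, a CD45-like control marker). Signal classes:

* `NUCLEAR_PLA_POS` — Gaussian-profile puncta (σ = radius/2, radius 1.5 px,
  peak amplitude 400 with log-normal sdlog 0.25 variation) at uniform random
  positions inside the nucleus; counts are zero-truncated Poisson (mean 5) —
  a cell carrying the punctate class has at least one rolling-circle product
  by definition.
* `MEMBRANAL_FP` — the same puncta confined to a 2-px ring at the cell
  boundary.
* `DIFFUSE_AF` — a uniform +80 elevation across the cell disk.
* `NEGATIVE` — no PLA signal.

Marker staining is uniform across the disk with log-normal cell-to-cell
levels (means 500/40/15 for CD80 across target-high/low/control; 400 vs 10
for CD45), which produces the bimodal separation the population gate relies
on. The probes-only control consists of negative cells carrying weak
membranal puncta (Poisson mean 2, amplitude 12) plus a +2 diffuse floor —
low-level nonspecific probe binding. Spillover is applied as linear mixing of
the noise-free stack; Gaussian read noise (sd 5) is added afterwards and
clipped at zero, so compensation is exactly recoverable in the noise-free
limit. Every draw is recorded in a ground-truth table, and a fixed seed
reproduces a sample exactly.

Defaults were chosen once so the four classes reproduce the qualitative
morphologies the cascade discriminates, with puncta bright relative to the
summed top-hat noise floor (a punctum integrates to ≈ 1400 intensity units
against a mask-wide noise-floor spread of a few hundred) — i.e. a
well-separated scenario. What the generator deliberately does **not** model:
optical point-spread functions, camera gain, doublets, cell-shape variation,
or spatially structured autofluorescence. Passing recovery tests on these
images therefore demonstrates the internal consistency of the operators and
cascade — not performance on real instrument data, where gate positions
(probes-only percentile, MCP cutoff, area range, BDS cutoff) are expected to
need recalibration against real controls. All of them are configuration
values, not constants.

## Numerical choices

* The morphological operators run on EBImage; grayscale images are rescaled
  by a power of two before opening (EBImage clips intensities to [0, 1];
  power-of-two scaling is exact in floating point, keeping integer-image
  top-hats exact). Two-valued images would silently take EBImage's binary
  path, so the grayscale opening is reconstructed from the binary opening of
  the upper level set in that degenerate case.
* Connected components are 4-connected (EBImage convention); the largest
  component wins, first label on ties.
* Adaptive erosion uses a 3×3 box element and stops at the last mask whose
  area is ≥ the retained-area target (percent 100 returns the base, percent 0
  the last non-empty erosion); a no-shrink guard prevents cycling on masks
  that touch the image border.
* MCP rings: 8 equal-width bins of normalized boundary distance from the
  Euclidean distance transform; the innermost ring wins ties; a mask with a
  single distance level (too thin to ring) returns 0.5 and large-scale
  consumers treat it as uninformative.
* Empty masks never produce silent zeros: features are 0/NA with a warning
  and a flag column in the feature table.
* The probes-only percentile is the type-7 sample quantile (R's default),
  documented because the gate reproduces it exactly in tests.
* Degenerate inputs: all-zero images give empty masks (warning); empty
  control samples and unassignable populations are refused with errors, not
  guessed.

## Problem sizes used in validation

The packaged tests validate each operator against naive brute-force
re-implementations (min/max scans, BFS flood fills, exhaustive distance
transforms) on 31×31 images — 200 random images per operator in the
acceptance suite, exact for integer-valued inputs — and exercise the full
pipeline at the acquisition scale the method targets: 1000 target-population
cells per sample with a planted 25% positive fraction (100 seeds), 600-cell
knockout-like samples containing only artifact classes, 400-cell probes-only
self-consistency runs, 200-cell single-stain compensation controls with a
planted 0.20 bleed, and 500 simulated null designs for the type-I error of
the experiment-level t-test. The end-to-end planted-difference recovery in
the regular suite uses a reduced 3-experiment × 2-replicate design at 150
cells per replicate.

## Known limitations

* The IDEAS software's exact definitions of AdaptiveErode, its BDS log base
  and clipping, and its Max Pixel background estimator are unpublished; the
  operators here implement the documented interpretations above and are not
  claimed to be numerically identical to IDEAS.
* The 2-D PLA gate is an axis-aligned conjunction; polygon gates are out of
  scope.
* Compensation is linear unmixing; nonlinear or autofluorescence-spectrum
  unmixing is out of scope.
* The nested design is analysed by averaging, as in standard practice for
  this assay, not by mixed-effects modelling.
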