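# plicr

Image cytometry feature extraction and gating for proximity ligation assays.

## The problem

A proximity ligation assay (PLA) converts a protein–protein interaction or a
post-translational modification into a bright fluorescent punctum per detected
event. Read out on an imaging flow cytometer (IFC), every cellular event comes
with a small multichannel image — brightfield, PLA signal, surface-marker
stains — so interactions can be quantified in rare, marker-defined
subpopulations (e.g. CD80-high thymic epithelial cells) as **the percentage of
PLA-positive cells per population per biological replicate**.

Naive intensity gating overcounts: nonspecific probe binding produces bright
*membranal* puncta, autofluorescent cells show a *diffuse* elevation, and
strong *channel bleed-through* survives compensation. `plicr` implements the
image-feature vocabulary and the multi-stage gating cascade that strip these
false positives, plus everything around them:

- **Feature operators** on per-cell pixel grids: Bright Detail Intensity
  (white top-hat, spot radius ≤ 3 px, summed in-mask), Max Pixel
  (background-subtracted maximum), Max Contour Position (radial position of
  the brightest concentric ring: 0 = center, 1 = perimeter), staining area,
  and Bright Detail Similarity (Fisher z of the bright-detail correlation of
  two channels, `0.5·log((1+r)/(1−r))`).
- **Masks**: the morphology mask (all pixels within the outermost contour)
  and its shape-aware adaptive-erode interior (retained-area percent, default
  78).
- **Spillover compensation**: matrix estimation from single-stain controls
  (median of background-subtracted channel-sum ratios) and pixelwise linear
  unmixing.
- **The gating cascade**: population assignment from marker intensities; a
  2-D PLA gate (BDI ∧ Max Pixel) set at the 99.5th percentile of a
  probes-only control; localization filtering (interior-mask re-gating, MCP ≤
  0.6 for nuclear targets, staining-area range); BDS > 1.5 exclusion of
  bleed artifacts. Full audit trail per cell.
- **Replicate statistics**: percent-positive per replicate, unweighted
  averaging to experiment-level group means, two-sided equal-variance Student
  t-test across independent experiments (± s.e.m.).
- **A synthetic single-cell image simulator** that plants nuclear-speckle
  positives, membranal and diffuse false positives, marker-defined
  populations, spillover and a probes-only background — with full ground
  truth — so the entire pipeline is testable without instrument data.

Results come back as tibbles; fitted objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

```r
library(plicr)

params <- scene_params()                    # 33x33 px, 4 channels
config <- gating_config("tec")              # full false-positive cascade

# a sample with 25% planted positives in the CD80-high population,
# plus the probes-only background control that sets the PLA gate
cells  <- simulate_sample(500, mix = population_mix(f_pos = 0.25),
                          params = params, seed = 42)
probes <- simulate_probes_only(200, params = params, seed = 43)

result <- run_pipeline(list(rep1 = cells), probes, config)
result
#> <plic_result> 500 cells, 1 sample(s)
#> PLA gate (99.5th pct of 200 probes-only cells): BDI > 1632, Max Pixel > 33.46
#> # A tibble: 3 × 5
#>   sample population      n n_pos pct_pla_pos
#>   <chr>  <chr>       <int> <int>       <dbl>
#> 1 rep1   CONTROL_POP   215     0         0
#> 2 rep1   TARGET_HI     179    39        21.8
#> 3 rep1   TARGET_LO     106     0         0
```

21.8% of the 179 CD80-high cells are called PLA-positive (39/179). The ground
truth of this draw planted exactly 39 nuclear-speckle positives in that
population: the raw 2-D gate picked up 58 cells, and the localization/BDS
filters removed the 19 membranal, diffuse and background false positives.
The control population and the CD80-low cells, which carry no planted
signal, stay at 0%. `tidy(result)` returns the per-cell
audit trail (every gate outcome and the reasons a cell was excluded);
`autoplot(result)` draws the per-population percentages.

Replicate-level comparison across independent experiments:

```r
replicates <- tibble::tibble(
  experiment  = rep(c("e1", "e2", "e3"), each = 2),
  group       = rep(c("WT", "KO"), 3),
  replicate   = paste0("m", 1:6),
  pct_pla_pos = c(24.1, 2.2, 26.8, 1.4, 23.0, 3.1))
cmp <- compare_groups(aggregate_replicates(replicates))
cmp
#> <plic_comparison> Student two-sample t-test on experiment-level means
#> # A tibble: 2 × 4
#>   group n_experiments mean_pct   sem
#>   <chr>         <int>    <dbl> <dbl>
#> 1 KO                3     2.23 0.491
#> 2 WT                3    24.6  1.13
#> t = -18.2, df = 4, two-sided p = 5.365e-05
```

A thin command-line front end over the same functions ships in
`inst/cli/plic` (`plic simulate`, `plic gate`, `plic quantify`).

## Scientific background

The methods vignette (`vignettes/plic-methods.Rmd`) documents the feature
definitions, the cascade, what the simulator does and does not emulate, every
numerical choice (background estimator, mask conventions, percentile rule,
tie-breaks, degenerate inputs), and known limitations.
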