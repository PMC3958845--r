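# fishstrat

Quantifies the three-dimensional stratification of ammonia-oxidizing
bacteria (AOB) and anammox bacteria in moving-bed biofilm reactor (MBBR)
carrier compartments from multi-channel FISH micrographs of biofilm
cryosections.

In a nitritation-anammox MBBR, AOB oxidize ammonium to nitrite in the
oxygenated outer biofilm and anammox bacteria consume that nitrite with
ammonium in the anoxic interior; process performance hinges on where the
two guilds sit inside the ~1 mm square carrier compartments. `fishstrat`
turns section images — a reference channel labelling all bacteria
(EUB338mix) plus specific-probe channels (Nse1472 = AOB, Bfu613 =
anammox) — into depth and wall-distance abundance profiles with
significance tests, and ships a synthetic image generator with exact
ground truth so every stage is verifiable.

## What it computes

For each section at depth *z*, the **biovolume fraction** of a probe
target is

```
f = area(specific-probe objects kept after artifact rejection) / area(reference signal)
```

after fixed-cutoff (default 30) or gradient-weighted RATS thresholding,
single-pass noise reduction (a foreground pixel needs >= 1 of 8
neighbours), reduction to a 1-megapixel budget, 8-connected
segmentation, removal of autofluorescent objects present in both
specific channels (>= 50% mutual overlap), and congruency rejection
against the reference (objects < 50% congruent dropped; image flagged
unless aggregate congruency >= 90%).

Horizontal stratification uses the **slicer**: pixels are binned into
concentric 100 um wall-distance shells (exact Euclidean distance to the
boundary baseline, smoothed over 20% of the side length), giving
per-shell fractions aggregated across sections as mean ± 95% t-CI.
Vertical trends are OLS fits of fraction on depth,

```
f(z) = a + b z,   H0: b = 0  (two-sided t-test; slope, R^2, n, p, alpha reported)
```

optionally inside a depth window. Compartment geometry (minimum-area
bounding rectangle), shrinkage versus physical carrier dimensions, and
the eight standard biofilm thickness measurements (side normals, corner
diagonals, narrow channels skipped) round out the image side; a
stoichiometry module covers reactor arithmetic (HRT, nitrogen balance,
the 11% nitritation-anammox nitrate ratio, depth coverage).

## Worked example

```r
library(fishstrat)

cfg <- synthetic_config(compartment_side_um = 1000, pixel_size_um = 4,
                        section_depths_um = seq(50, 800, by = 50), seed = 42)
stack <- generate_compartment_stack(cfg)

res <- run_pipeline(pipeline_config(stack$sections, downscale_mp = NULL,
                                    windows = list(anammox = c(180, 400)),
                                    compartment_side_um = 1000))
print(res)
#> <pipeline_result> 16 sections
#>   AOB : <depth_trend> Nse1472 window [50, 800] um
#>   slope -4.925e-04 per um, R^2 = 0.987, n = 16, p = 1.12e-14 (alpha = 0.01, significant)
#>   anammox : <depth_trend> Bfu613 window [180, 400] um
#>   slope 1.608e-03 per um, R^2 = 0.992, n = 5, p = 0.0003 (alpha = 0.01, significant)
```

The generator planted AOB decreasing 0.40 → 0.05 over 0-800 um and
anammox rising 0 → 0.30 between 180 and 400 um; the pipeline recovers a
significantly negative AOB depth slope over the full range and a
significantly positive anammox slope inside the window. Shell profiles
(here for a depth-stratified, wall-independent configuration, so the
shells agree within their CIs):

```r
head(res$shell_summary[res$shell_summary$probe == "anammox", ], 3)
#>   shell_index d_lo_um d_hi_um   probe  n      mean     ci_lo     ci_hi
#> 1           0       0     100 anammox 16 0.2499291 0.1597820 0.3400763
#> 2           1     100     200 anammox 16 0.2287942 0.1502322 0.3073562
#> 3           2     200     300 anammox 16 0.2387156 0.1593619 0.3180692
```

Reactor arithmetic:

```r
depth_coverage_percent(800, 2000)   # 80  (% of a 2 mm carrier's half-depth)
anammox_stoichiometric_ratio()      # 11  (% NO3- produced per NH4+ removed)
hrt(7.5, 1.2, report = TRUE)        # 6.3 (h)
```

With `out_dir` set, `run_pipeline()` writes depth profiles, regressions,
shell profiles, geometry, shrinkage, QC and object tables as versioned
CSVs plus a YAML run log recording every threshold actually applied. A
thin command-line wrapper lives at `inst/scripts/fishstrat.R`
(subcommands `generate`, `run`, `stoich`).

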