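---
title: "Quantifying biofilm stratification from FISH sections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biofilm stratification from FISH sections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Nitritation-anammox moving-bed biofilm reactors (MBBRs) remove nitrogen
through a division of labour: aerobic ammonia-oxidizing bacteria (AOB)
convert ammonium to nitrite in the oxygenated outer biofilm, and anammox
bacteria consume that nitrite together with ammonium in the anoxic
interior. Whether a reactor works therefore depends on *where* the two
guilds sit inside the ~1 mm square protected compartments of the plastic
carriers. `fishstrat` quantifies that spatial organization from
multi-channel fluorescence in situ hybridization (FISH) micrographs of
biofilm cryosections: a reference channel labelling essentially all
bacteria (the EUB338 probe mix) plus one channel per specific probe
(Nse1472 for *Nitrosomonas europaea/eutropha*-lineage AOB, Bfu613 for
*Ca. Brocadia fulgida*-related anammox).

The core quantity is the **biovolume fraction**: the area of a specific
probe's signal divided by the reference-probe area in the same region.
Computed per section (at depth *z* into the compartment) it gives the
vertical profile; computed per concentric wall-distance shell (the
"slicer" analysis) it gives the horizontal profile.

## The measurement chain

Each section image passes through a fixed sequence, every step of which
is a small, separately tested function:

1. **Thresholding.** Either a fixed 8-bit cutoff (default 30) or
   gradient-weighted robust automatic threshold selection (RATS):
   `T = sum(w * I) / sum(w)` with `w` the local gradient magnitude, so
   edge pixels — whose intensities straddle the background/foreground
   transition — dominate. The comparison is inclusive (`>= T`), so a
   cutoff of 30 keeps pixels at exactly 30; the alternative convention
   would differ only on exact-valued pixels. A flat image has no defined
   RATS threshold and raises an error. A tile-local RATS variant
   (`tile_px`) is available for unevenly illuminated images; the global
   form is the default because the plain gradient-weighted mean is the
   only formulation that is unambiguous without further specification.
2. **Noise reduction.** One pass over the binary mask: a foreground
   pixel survives iff its 8-neighbourhood contains at least 1 foreground
   pixel. All decisions are made against the input mask — the single-pass
   semantics is the contract, so removing one pixel never cascades.
3. **Resolution budget.** Assembled wall-to-wall images are large;
   biovolume fractions are measured after area-mean downscaling to 1
   megapixel. We use the binary convention 1 Mpx = 2^20 pixels, under
   which a 4096^2 image reduces by an exact integer factor of 4 to
   1024^2. Area-mean resampling conserves foreground area fractions
   (tested to ±0.01 after re-thresholding); images within budget are
   never upscaled.
4. **Segmentation.** Maximal 8-connected components. Internally,
   4-connected labelling (`EBImage::bwlabel`) is extended by a
   union-find merge of diagonally adjacent labels; the result is checked
   against a flood-fill oracle in the tests. Segmentation partitions the
   mask, so object areas always sum to the mask area.
5. **Dual-channel autofluorescence removal.** Autofluorescent particles
   appear in both specific channels, which no genuine cell can (the
   probes target disjoint taxa). An object is removed iff at least 50%
   of its own area overlaps the other specific channel's foreground,
   symmetrically in both channels. The 50% rule (rather than "any
   overlap") avoids deleting genuine colonies that merely abut across a
   channel-registration error.
6. **Congruency rejection.** The congruency of an object is the
   fraction of its area inside the reference mask. Objects below the
   50% object threshold are rejected; the image then passes QC iff the
   aggregate congruency of the kept objects (kept area inside the
   reference over total kept area) is at least 90%. A failing image is
   flagged, never silently dropped — dropping sections would bias the
   depth profiles. The 90% rule is applied per image; applying it per
   batch would let one bad image hide inside a good batch.
7. **Fractions.** Kept specific area over reference area. A value above
   1 is an error, not a clamp: it can only arise if congruency filtering
   was skipped.

## The slicer: horizontal stratification

The compartment footprint is stratified into concentric shells of
100 um wall distance. The boundary polygon of the footprint is traced
(Moore neighbour tracing), optionally smoothed with a circular moving
average whose window spans a fraction (default 20%) of the compartment
side length, rasterized back to pixels, and every interior pixel is
labelled `floor(d / 100 um)` where `d` is its exact Euclidean distance
to the nearest baseline pixel (computed by distance transform, verified
against an all-pairs oracle). The smoothing step exists because a traced
pixel boundary is ragged at the pixel scale; measuring distance from a
smoothed baseline is the natural reading of "baseline smoothing", and
the fraction is an exposed parameter since other conventions are
conceivable. Distance is measured from the compartment wall, not from
the biofilm-water interface: the concentric bands are anchored to the
compartment geometry, which is what the wall-to-wall images cover.

Shells partition the footprint exactly (an invariant the tests assert);
the innermost shell may be thinner than 100 um and is reported with its
true range. Per shell, the biovolume fraction is specific area over
reference area *within the shell*; shells with no reference signal are
reported missing, never zero. Across sections, shells are aggregated as
mean ± t-based 95% CI with a per-shell `n` — deep shells are reached by
fewer sections, and their `n` shrinks accordingly rather than being
padded.

## Geometry, shrinkage, thickness

Compartment dimensions come from the minimum-area bounding rectangle
(rotating calipers over the convex hull) of the reference signal, with
one pixel size added per projected extent so pixel *extents*, not pixel
*centres*, are measured. Shrinkage is the ratio of measured to physical
carrier dimensions, reported per depth because the carrier compartment
narrows slightly toward its mid-depth "waist". Thickness follows the
eight-measurement convention — one along the inward normal at each side
midpoint, one along the inward diagonal at each corner — with gaps
narrower than a configurable channel width (default 10 um) skipped, as
biofilm channels are not absence of biofilm. Side rays are capped at
half the side (a fully grown compartment measures side/2, where the
bands meet); corner rays at half the diagonal. These ray directions are
the natural reading of "one from each side and corner"; an operator
with a ruler tool might have chosen slightly different lines, which is
why the fixture tests assert recovery within one pixel rather than
exactly.

## Depth trends and their calibration

Vertical stratification is summarized by ordinary least squares of
biovolume fraction on depth, optionally inside a depth window (for a
population like anammox that only establishes below a threshold depth,
the window is where a linear trend is meaningful). Significance is the
two-sided t-test on the slope — equivalent to the F-test in simple
regression; reported values are slope, R², n, p and the chosen alpha.
Perfectly constant input is reported as slope 0, R² = 0, undefined p.
Windows are explicit parameters, never hard-coded.

`trend_recovery_experiment()` closes the loop: it generates synthetic
stacks with known stratification and checks that the full pipeline
recovers the planted slope signs and R². Its `method = "sampling"` path
draws per-section fractions from the generator's colony-sampling model
(same colony counts, positions, radii and class draws) without
rasterizing images. This is the appropriate route for large-replicate
calibration — e.g. confirming the trend test holds its ~5% size under
flat profiles across 200 replicates — because the property being
calibrated belongs to the test statistic, not to the rendering; the
image path is exercised by the 20-seed recovery experiment instead.

## The synthetic generator: what it emulates, and what not

The generator renders the study conditions at configurable scale:
square ~1 mm compartments at 3.30 px/um by default, 41 sections every
20 um down to 820 um, AOB falling linearly 0.40 → 0.05 over 0-800 um,
anammox rising 0 → 0.30 between 180 and 400 um and constant below,
biomass areal density rising with depth to 400 um, colony radii ~N(12,
4²) um (microcolonies of varying size; no published size statistics
exist, so this is a stated stand-in, exposed in the config), corner
placement density scaled by 336/235 (the observed corner/side thickness
contrast), Poisson(5) autofluorescent artifacts per section with
identical footprints in both specific channels, and 2 isolated speckle
pixels per 10^4. Foreground intensity ~N(180, 30²), background ~N(10,
3²) — straddling the cutoff of 30 so thresholding is genuinely
exercised — with a 0.7 px Gaussian edge blur.

Design points worth knowing:

* Colony classes partition the biomass with P(AOB) and P(anammox) given
  by the target profiles at the colony centre and all remaining
  probability on "other" (reference-only) biomass. Measured fractions
  then equal the targets in expectation; the configured
  `other_bacteria_fraction` is a floor that enters the
  `aob + amx + other <= 1` validation, which rejects inconsistent
  configurations naming the offending depth and wall distance.
* A row of wall-lining colonies guarantees the biomass reaches the
  compartment walls (as attached biofilm does), which is what makes the
  compartment measurable from the reference signal to within 1%.
* Artifacts are placed in biomass-free voids (with a 2 px margin).
  Contact would merge an artifact with a genuine colony into one
  8-connected object, making "remove exactly the planted artifacts"
  ill-posed; physically, the typical autofluorescent mineral or debris
  particle is not embedded inside a microcolony.
* Ground truth is a single mutually exclusive label grid per section
  (later-painted colonies own shared pixels), so true fractions are
  exact pixel counts, and `expected_profile()` provides the analytic
  expectation by integrating the target functions over the pixel grid —
  computed from the config, never from images.
* A fixed seed makes the stack bit-identical; all randomness flows
  through one RNG stream.

What the generator does **not** emulate: real microscope noise
(Poisson shot noise, bleed-through, uneven illumination, focus drift),
irregular colony shapes, the biofilm-water interface geometry of young
biofilms, erosion structures, or any growth dynamics. Passing the
recovery tests therefore shows the *measurement chain* is correct and
unbiased under the stated image model — it does not certify performance
on arbitrary real micrographs, where thresholding choices dominate.

The deterministic ring fixture (`render_biofilm_ring()`) is separate
from the stochastic generator: a noise-free wall-attached band with
side thickness 235 um and corner thickness 336 um (the published
mature-biofilm values), built so both numbers are recovered exactly
along the measurement rays. It backs the geometry and shrinkage tests
(including the 10% linear shrink → 0.81 area ratio check).

## Reactor arithmetic

The stoichiometry module carries the desk-scale numbers. With anammox
consuming 1.32 mol nitrite and producing 0.26 mol nitrate per mol
ammonium, and nitritation supplying exactly the nitrite consumed, the
expected nitrate production per total ammonium removed is
0.26 / (1 + 1.32) = 11.2% → 11%; this is checked against a two-reaction
mass-balance oracle for arbitrary coefficients. The nitrogen balance
conserves N exactly by construction. Depth coverage divides the deepest
section by *half* the carrier depth, because sectioning proceeds from
each surface to the mid-plane waist: 800 um covers 80% of a 2 mm and
53% of a 3 mm carrier. Reported percentages round half away from zero
(6.25 h → 6.3 h); base R's round-half-to-even would report 6.2.

Note that a reactor time series averaged day by day does not reproduce
the ratio of the averaged concentrations: `nitrogen_balance()` computes
the latter from a single record, and the two can legitimately differ by
a point or two.

## Numerical choices and problem sizes

Tolerances and sizes used in the test suite are the package's own
choices: oracle-equivalence tests run exhaustively on grids up to
50×50 (where all-pairs distance and flood fill are affordable); OLS is
checked against the normal equations at 1e-10 relative; synthetic
recovery runs 1000 um compartments at 4 um/px (250² px) with 20
sections, which keeps a 20-seed full-pipeline experiment around a
minute while leaving per-section binomial sampling noise (sd ≈ 0.02)
small against the planted trends. The vertical profiles in the
recovery experiment use one observation per section, treating sections
as independent samples of the depth profile.

Known limitations: no watershed declumping (touching microcolonies are
one object — irrelevant for area fractions, relevant if object counts
were wanted); no cross-correlation stitching (tile offsets must be
known); shells are computed per section, never as 3D shells across
sections; and the RATS tile-local variant is a plain per-tile
computation without interpolation across tile seams.
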