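---
title: "Radial profiling, lysosome positioning and colocalization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial profiling, lysosome positioning and colocalization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoradial)
```

## The measurement problem

Many questions about membrane traffic reduce to *where* an organelle
population sits inside the cell: late endosomes and lysosomes cluster near
the nucleus in some states and redistribute toward the plasma membrane in
others, and their luminal pH tracks that position. cytoradial quantifies
this from multi-channel 2D fluorescence images with three instruments:

1. a **radial intensity profile** — concentric annuli around each nucleus,
   clipped to the cell envelope, each annulus reporting its share of a
   punctate marker's total signal;
2. a **per-particle positioning and pH-proxy readout** — segmented puncta
   (e.g. dextran-loaded lysosomes) with a ratiometric two-channel
   intensity ratio, binned by normalized radial position into quartiles;
3. a **masked Pearson colocalization** between channel pairs.

Everything operates on plain matrices (one per channel) under one
convention: pixels are (row, col), 0-based in exported tables, a pixel's
position is its center, distances are Euclidean between pixel centers and
reported in pixels (times the pixel size when one is supplied).

## Radial profiles

The cell envelope mask comes from a diffuse cytoplasmic channel
(projection, optional CLAHE, automatic global threshold, hole filling,
size filter); nuclei come from the nuclear stain (threshold, connected
components, size filter, optional watershed). Both can be replaced by
precomputed masks — the package's substitute for interactive manual
correction.

Each cytoplasm pixel joins the *territory* of its nearest nucleus
(Euclidean distance, ties to the lower label). Within a territory, annuli
are level sets of the distance-from-nucleus transform:

* annulus $k$ of $n$ collects pixels with $d \in ((k-1)\,d_{max}/n,\;
  k\,d_{max}/n]$, where $d_{max}$ is the territory's maximum
  distance-from-nucleus — the nucleus-to-periphery distance that
  normalizes radial position, so $r_{norm} = 1$ is the cell periphery in
  every cell;
* a fixed-thickness mode ($k = \lceil d/t \rceil$, final partial annulus)
  is available; its $r_{norm}$ is normalized by the same $d_{max}$.

Level sets rather than repeated morphological dilation: the limit geometry
is identical, but level sets avoid structuring-element anisotropy and give
exact half-open bins. The nucleus interior is never part of an annulus.

Per annulus we report area, **intensity fraction** — the annulus's share
of the territory's total background-subtracted signal, so fractions sum
to 1 and profiles are comparable between cells — and **intensity
density** (integrated background-corrected signal / area). Background is
the median intensity outside the cell mask, subtraction clipped at zero;
`background_mode = "none"` disables it. A territory with zero total
signal reports fractions of 0 and `signal_valid = FALSE` rather than NaN.

Defaults: 10 fractional annuli; Otsu thresholding (the common ImageJ
default) with triangle and fixed alternatives; max projection for stacks;
8-connectivity (ImageJ particle-analysis behavior); strict `>` at every
threshold, so ties go to background.

## Lysosome positioning and the pH proxy

Particles are segmented from the pH-insensitive channel by a local-mean
adaptive threshold (odd `block`, additive `offset`; windows are clipped at
the image border so a whole-image block reduces exactly to global-mean
thresholding) followed by connected-component analysis with an area
filter. Per particle: area, unweighted centroid, per-channel mean
intensities, and the ratio pH-sensitive / pH-insensitive. Particles whose
denominator mean is at or below `den_floor` are excluded rather than
epsilon-inflated, which would distort the ratio statistic.

Position is measured from the centroid in straight lines: $d_{nuc}$ to
the nearest nucleus pixel (0 inside a nucleus), $d_{pm}$ to the nearest
out-of-mask pixel, and

$$u = \frac{d_{nuc}}{d_{nuc} + d_{pm}} \in [0, 1],$$

0 at the nuclear membrane, 1 at the plasma membrane; $u$ is invariant to
uniform image scaling. Quartile bins are $[0, .25], (.25, .5], (.5, .75],
(.75, 1]$, labeled 0.25/0.50/0.75/1.0 — upper edges belong to their bin
and $u = 0$ is in the first bin. The per-cell per-quartile mean ratio is
the arithmetic mean over valid members; empty quartiles are omitted, not
imputed. Particles overlapping nuclei or outside the mask are flagged
(`in_nucleus`, `in_mask`) and retained or excluded explicitly, never
silently. Group comparison statistics (ANOVA etc.) are deliberately out
of scope — the tables feed external statistical software.

## Colocalization

`pearson_coloc()` is the standard Pearson correlation over masked pixel
pairs. A channel constant within the mask raises an error instead of
reporting 0 — a constant channel has no defined correlation, and
substituting 0 would contaminate downstream summaries. Stacks should be
z-projected first (`project_stack()`), or pooled plane-wise if the whole
volume is wanted. Manders coefficients and Costes thresholding are not
implemented.

## The synthetic-scene generator

`generate_scene()` renders the five channels (envelope, nuclear, signal,
ratio numerator, ratio denominator) for fields of circular cells with one
concentric circular nucleus each, placed on a jittered grid so cells
never overlap. Geometry is circular on purpose: the ground truth (masks,
punctum radii $u$, per-punctum ratios) stays analytic and exact. Puncta
sit at normalized radius $u \sim \mathrm{Beta}(\alpha, \beta)$ between
the nuclear border ($u=0$) and the cell border ($u=1$); the two-parameter
Beta family spans perinuclear, uniform and peripheral regimes. The
envelope channel is graded (brighter perinuclearly, dimmer at the
periphery, as for reticular ER markers), which is exactly the situation
contrast-limited equalization is meant for on real data.

The pH-proxy scenario renders the same puncta into both ratio channels:
denominator amplitude fixed, numerator amplitude $= \mathrm{den} \times
(r_0 + r_1 u)$ with defaults $r_0 = r_1 = 0.5$, so the true ratio rises
linearly from 0.5 at the nuclear membrane to 1.0 at the periphery —
peripheral lysosomes read out as less acidic, the direction reported for
dextran-FITC / dextran-647 ratios in live cells.

Noise is shot noise plus read noise: $I \mapsto
\mathrm{Poisson}(g I)/g + \mathcal{N}(0, \sigma)$, clipped at 0, with
defaults $g = 50$, $\sigma = 2$ against amplitude-100 puncta. Dividing
the Poisson count by the gain keeps channels on the amplitude scale
(making $\sigma = 2$ meaningful) and cancels out of every ratio. All
randomness flows from one seed through Mersenne-Twister with inversion
sampling for normals, so identical (spec, seed) pairs are byte-identical.

Default study conditions: 1024×1024 px, 20 cells (radius 55 ± 4 px,
nucleus 14 ± 1.5 px), 500 puncta per cell of Gaussian sd 1.5 px. The
packaged `scenario("wt")` uses Beta(2, 5) (perinuclear retention of the
late-endosome marker) and `scenario("ko")` Beta(5, 2) (peripheral
redistribution); their analytic annulus masses come from
`beta_bin_masses()` and the closed-form quartile means of the linear
ratio model from `quartile_expectations()`.

What the generator does *not* emulate: realistic PSFs, reticular ER
texture, non-convex cell shapes, 3D structure, chromatic shifts, or
autofluorescence. Passing the packaged checks therefore demonstrates that
the *measurement machinery* is correct on data whose answer is known —
not that segmentation parameters transfer to any particular microscope or
cell type, which always needs visual inspection of the masks.

## Numerical choices

* Distance transforms are exact Euclidean (verified against an exhaustive
  $O(N^2)$ oracle); nearest-nucleus assignment resolves exact ties to the
  lower label, making territories deterministic.
* Component labels are assigned 1..K in raster order of each component's
  first pixel, so labeling never depends on library internals.
* Annulus bins are half-open $(lo, hi]$; a pixel exactly on an edge lands
  in the inner annulus. Thresholds are strict `>` everywhere.
* CSV exports render doubles with 12 significant digits and sort rows by
  their key columns; identical runs are byte-identical.
* Degenerate inputs have defined behavior: constant images threshold to
  all-background with a warning, an all-foreground mask treats the frame
  edge as background, an empty cell mask is an error, zero-signal
  territories and zero-denominator particles are flagged.

## Validation problem sizes

The packaged checks (tests and `scripts/acceptance.R`) use: 100 random
8×8 masks against the brute-force distance oracle; 50 random single-cell
scenes for annulus conservation; 100 random masked pairs for the Pearson
formula; the two 20-cell/500-puncta scenarios for profile recovery (max
annulus-mass error ≤ 0.05, peripheral shift of the intensity-weighted
mean $r_{norm}$ ≥ 0.2); 2000 uniform particles for quartile means (within
5% of the closed form) plus 100 replicates of 200 particles for monotone
ordering; one noise-free 6-cell scene for segmentation Jaccard; and a
duplicate simulate→profile→lyso run for byte-level determinism. Profile
recovery is computed from the ground-truth masks so it isolates the
profiling machinery; segmentation fidelity is checked separately.

## Known limitations

* Distances are straight-line, not geodesic: in strongly non-convex cells
  the shortest path to the membrane may cross the background.
* Multi-cell fields are partitioned by nearest nucleus, which is only an
  approximation of true cell boundaries when cells differ greatly in
  size.
* The adaptive-threshold particle detector merges touching puncta; dense
  perinuclear fields under-count particles (ratios remain intensity-
  weighted means over the merged region).
* Intensities are treated as arbitrary linear units; no absolute pH
  calibration is attempted — the ratio is a relative proxy only.
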