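---
title: "Quantifying per-islet insulin secretion from tiled fluorescence time-lapse imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying per-islet insulin secretion from tiled fluorescence time-lapse imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A fluorescent C-peptide reporter is stored in the insulin secretory
granules of every β-cell, so the total fluorescence of an islet is
proportional to its stored insulin. Secretion removes reporter together
with insulin; nothing in the imaging window synthesizes or bleaches
appreciable amounts of it. The quantity tracked per islet is therefore
the **integrated density**

$$\mathrm{ID}_i(t) = \sum_{p \in M_i(t)} I(p, t),$$

the sum of *raw* pixel values over the islet's mask, and every response
statistic is a ratio of integrated densities, which cancels the unknown
proportionality between fluorescence and insulin mass:

* per-islet percent of reference, $P_i(t) = 100\,\mathrm{ID}_i(t) /
  \mathrm{ID}_i(t_\mathrm{ref})$, with $t_\mathrm{ref}$ the stimulation
  time (the last low-glucose point, t15, for the in vitro protocol; t0
  for the in vivo challenge);
* the total response $100\,(\sum_i \mathrm{ID}_i(t_\mathrm{ref}) -
  \sum_i \mathrm{ID}_i(t_\mathrm{end})) / \sum_i
  \mathrm{ID}_i(t_\mathrm{ref})$, algebraically the content-weighted mean
  of the per-islet declines (asserted in the tests to $10^{-9}$
  relative);
* the **heterogeneity SEM**, the standard error of the mean of the
  $P_i(t_\mathrm{end})$, which is small when islets respond in lockstep
  and large when some islets secrete sharply while neighbors do not.

Assumptions worth stating: depth attenuation by overlying tissue scales
an islet's fluorescence by an unknown constant, but that constant cancels
in $P_i$; islet position is effectively fixed over the 15–60 minute
window apart from small rigid motion; and two islets merged by the mask
are treated as one object rather than split, so "islet" means "islet or
small cluster".

## Pipeline stages and their parameters

**Burst frame selection.** Breathing blurs an unpredictable subset of
frames, so each field is captured as a burst (5 frames, 250 ms apart, by
default) and the sharpest is kept. Sharpness is the variance of the
3×3-Laplacian-filtered image — zero for a constant image, invariant to
additive offsets, and strongly reduced by directional motion blur. Ties
go to the earliest frame. If every frame of a burst is blurred the best
one is still used but flagged `low_confidence` (detected as a best score
below half the tile's median best score across time points); downstream,
objects touching such tiles carry the flag, mirroring a policy of
discarding artifact objects rather than whole time points.

**Stitching.** Tiles overlap by 15 %. Each tile is registered to its
left (or top) neighbor by phase correlation of the overlap strips; the
fixed-side strip is extended by the search window so every candidate
shift compares a fully contained copy, which makes the correlation peak
an exact delta rather than one eroded by edge mismatch. The integer
offset maximizing the correlation within ±16 px of the nominal offset is
taken (the window covers the worst-case sum of two per-tile jitters);
ties break toward the nominal offset, then row-major order. Offsets are
chained from the anchor tile along a spanning tree — with ~6 tiles a
global least-squares refinement has nothing to add — and registration is
integer-pixel only, since at 0.54 µm/px sub-pixel shifts are immaterial
at islet scale. Overlap pixels are resolved by a Voronoi seam (nearest
tile center), so every mosaic pixel is a verbatim camera value; blending
would corrupt integrated densities.

**Segmentation.** The background is estimated by the rolling-ball
construction: grayscale opening by a flat disc of radius 200 px (larger
than any common islet radius; configurable for outliers). For radii
above 32 px the opening runs on a block-minimum-shrunken image and is
re-expanded bilinearly — the standard large-radius strategy — and the
image is edge-padded by replication so the estimate is unbiased at the
borders. Thresholding of the corrected image defaults to Otsu computed
on `log1p` intensities, floored at median + 6 MAD of the corrected
image. Two measured failure modes of plain linear-scale Otsu motivated
this: with depth attenuation spanning 0.4–1.0 the foreground is spread
over a ~4× intensity range and Otsu places the threshold *inside* it,
silently discarding the dimmest (deepest) islets; and on nearly empty
fields Otsu splits the background noise itself. The log transform
compacts the foreground into one mode, and the MAD floor makes empty
fields yield empty masks. A fixed-threshold mode remains for
reproducibility studies. Masks are hole-filled, connected regions use
8-connectivity, and regions smaller than
$\mathrm{round}(\pi (d_\mathrm{min}/2/0.54)^2)$ px are removed
($d_\mathrm{min}$ = 10 µm in vivo → 269 px; 20 µm for in vitro wells).
A constant image produces an explicit no-foreground mask, not an error.
Measurement is *redirected*: areas and centroids come from the mask, but
integrated density is an exact integer sum over the original image
(tested against a brute-force oracle).

**Tracking.** Islets barely move between time points (rigid jitter of a
few pixels), so linking is a minimum-total-cost one-to-one assignment on
centroid distance — solved as a maximum-weight bipartite matching, which
is order-independent where greedy nearest-neighbor is not — gated at
30 px displacement and 2× area ratio. Unmatched objects terminate or
open traces; no gap bridging is attempted, so an islet that disappears
and reappears yields two incomplete traces (both excluded from
statistics, retained for audit). A new mid-experiment trace whose
admissible predecessor was claimed by another object is flagged
`merge_suspect`. Exclusion reasons, in order of precedence: any member
within 20 px of the field edge; any saturated member (pixel at 4095);
incompleteness. A zero reference density excludes a trace with reason
`zero_reference` instead of dividing by zero.

**Statistics.** SEMs use the sample (n−1) standard deviation; a single
islet reports a missing SEM rather than zero. The heterogeneity
comparison runs Shapiro–Wilk on each group (a zero-variance group counts
as failing normality), uses an unpaired t-test when both pass at
α = 0.05 and a Mann–Whitney test otherwise, and reports both test
results either way. The size–response relation is a Spearman correlation
between area and log ID ratio, reported with its p-value and never
thresholded into a verdict; constant areas report a missing correlation.

## The synthetic-acquisition model

The simulator provides ground truth for every stage: a label map,
per-islet latent content traces, true tile offsets, and per-frame blur
flags. Its ingredients:

* **Islets** are soft-edged disks (1 px anti-aliased rim). Diameters are
  log-normal — the accepted right-skewed shape — truncated to a
  configured range; baseline fluorophore density is uniform in
  2400–3400 (12-bit units), and in vivo presets draw a per-islet depth
  attenuation uniform in [0.4, 1.0]. Content starts at density × area
  and falls *only* by secretion: each phase removes its release fraction
  multiplicatively, spread evenly over the phase's 5-min imaging
  intervals. In the homogeneous regime every islet releases the phase
  fraction exactly; in the heterogeneous regime per-islet fractions are
  drawn from a mixture of a barely-secreting component (Beta(1, 99)) and
  a responsive component (Beta(2, 8), releases up to ~50 %), with the
  mixture weight solved so the expected fraction equals the target —
  independent of size and position by construction.
* **Background** is static tissue autofluorescence: mean 20 with three
  zero-mean Gaussian-filtered white-noise fields at scales 160, 16 and
  3 px (amplitudes 10, 10, 12). The multi-scale texture matters: real
  tissue carries cellular-scale structure, and without the fine
  component the overlap strips hold too little registerable signal.
  Filtered white noise is used rather than an interpolated coarse grid
  because grid interpolation leaves a knot lattice whose creases
  phase-correlate spuriously at lattice-aligned lags.
* **Acquisition**: tiles are crops of the scene at nominal grid
  positions plus per-(time point, tile) integer jitter (σ = 2 px in
  vivo, clamped at ±8); blur-flagged burst frames (probability 0.3 in
  vivo) are convolved with a random-angle line kernel of length 5–15 px;
  then shot noise (variance = signal, in its normal approximation —
  exact at these count levels) plus σ = 3 read noise is added, and the
  result is rounded and clipped into [0, 4095]. Structural randomness is
  drawn once under the experiment seed; each frame's noise comes from a
  seed derived from its coordinates, so frames are bit-identical across
  runs regardless of access order.

The presets encode the study conditions: `invitro_gsis` (50 islets, one
field, phases low/high/low/KCl at 15 min each, 10 % release in high
glucose and a KCl fraction of 0.025/0.9 so the cumulative loss is
exactly 12.5 % of the pre-stimulation value), `invivo_gsis` (2×3 tiles,
80 islets, heterogeneous fractions with an expected 8 % total response
over 15 min), `invivo_fullpancreas` (200 well-separated interior
islets), and `stability` (45 min, all fractions zero).

What the simulator does **not** model: optical point-spread functions,
vasculature and innervation, sub-islet structure, insulin plasma
kinetics, content gains (some small islets appear to gain content in
real data — treated there as measurement variability, and not
synthesized here), non-rigid tissue deformation, and illumination
falloff across tiles. Passing tests therefore show that the measurement
chain is correct under rigid motion, realistic noise and wide dynamic
range — not that it is robust to deformation or optics effects absent
from the model.

## Problem sizes and validation design

Simulations are scaled so a full validation sweep runs on a laptop-class
single CPU: fields of 800×960 px in vitro, 2×3 mosaics of 512×640 px
tiles in vivo (1100×1344 px for the 200-islet capacity setting), and
islet diameters drawn with medians of 25–30 µm within the configured
ranges, all at the native 0.54 µm/px. These sizes keep every experiment
a faithful miniature: multiple tiles, dozens-to-hundreds of islets,
phase schedules at the real 5-min cadence.

Validation follows a recovery design. The in vitro preset embeds a known
10 % homogeneous release; the full pipeline (frame selection through
statistics) must recover it within 1 percentage point over 20 seeds —
likewise 12.5 % cumulative, and 8 % total response in vivo over 12
seeds. A graded-diameter series (6–50 µm) establishes that 10 µm is the
smallest diameter detected in ≥95 % of 50 replicates. The capacity
setting must yield exactly 200 complete traces mapping one-to-one onto
ground-truth labels. Structural invariants are tested exactly: integer
equality of integrated densities against brute-force sums, assignment
against exhaustive matching, recovered offsets against constructed
crops, and the weighted-mean identity of the total response.

Residual biases are understood and small: background fluorescence under
the mask dilutes percent declines by ~0.7–2 % of their value (hence
recovered means of ~9.9 rather than 10.0), and the mask's soft-edge
cutoff costs under 2 % of an islet's signal at the 20 µm scale,
cancelling almost entirely in the ratios.

## Known limitations

Touching islets are measured as one object (no watershed splitting);
traces do not bridge gaps; merges and splits are flagged, not resolved;
registration assumes the grid topology is correct at the nominal overlap
and only refines within ±16 px; and the CLI wraps the R API thinly —
anything beyond `simulate`/`run`/`report` is meant to be driven from R.
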