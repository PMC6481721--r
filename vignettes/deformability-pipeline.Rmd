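---
title: "Measuring single-cell deformability in microchannel flow: methods and design"
author: "DeformCyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-cell deformability in microchannel flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DeformCyto)
```

## The measurement

Cells driven by a constant pressure through a constricted rectangular
microchannel (width $W = 18\,\mu m$, height $H = 19.8\,\mu m$, test-section
length $L = 230\,\mu m$ by default) elongate from near-spheres into
bullet-like shapes. High-speed brightfield imaging (15 000 frames/s,
effective pixel size $0.97\,\mu m$, 1 µs exposure so ~0.3 m/s motion is
blur-free) records each transit across a region of interest extending five
channel widths beyond the test section on each side. The shape readout per
frame is the deformation index

$$DI = 1 - \frac{2\sqrt{\pi A}}{p},$$

with $A$ the projected area and $p$ the perimeter of the cell outline. $DI$
is zero for a circle, scale-invariant, and equals $1-\sqrt{4\pi A/p^2}$
(one minus the square root of circularity). Per cell, the pipeline reports:

* the **undeformed diameter** $D_c = 2\sqrt{A/\pi}$ from the mean area over
  all usable frames *before* the cell enters the test section ($x<0$);
* the **confinement** $D_c/D_h$, with $D_h = 2WH/(W+H)$ the hydraulic
  diameter ($18.86\,\mu m$ for the default geometry);
* the **deformability** $DI_{max}$, the maximum DI over frames whose
  centroid lies inside the test section ($0 \le x \le L$) — cells reach
  their maximum deformation before exiting and partially relax afterwards;
* the mean transit **velocity**, the least-squares slope of centroid
  position against time.

Population statistics are computed on cells gated to $0.85 < D_c/D_h <
0.95$ (open interval): below the gate cells deform too little to resolve,
above it they risk wall contact. Because gated $DI_{max}$ distributions are
log-normal rather than normal, samples are compared with one-tailed
Mann-Whitney U tests (significance level 0.01; tiers `ns` $p>0.01$, `*`
$p<0.01$, `**` $p<0.001$, `***` $p<10^{-4}$, `****` $p<10^{-5}$ — the `*`
rung is an extension that makes the ladder total, reference usage jumps
from `ns` to `**`).

## Coordinate frame and geometry

All positions are physical micrometres with $x=0$ at the test-section
entrance plane, $x=L$ at the exit, flow in $+x$, and $y=0$ on the channel
centreline; the ROI spans $[-mW, L+mW]$ for a margin of $m$ channel widths
(default 5). Rasterisation and measurement share a 0-based pixel-centre
convention (column $j$ is centred at $x_{min}+(j+0.5)\,px$), which makes the
physical↔pixel round trip exact and subpixel centroids meaningful. Geometry
and acquisition parameters travel together in one JSON/YAML config
(`readAnalysisConfig()`); downstream code never sees raw constants. Whether
positions are cell-centroid or leading-edge positions is not fixed by the
measurement definition; the centroid is used throughout, being what polygon
first moments deliver.

## Image processing

Per recording, a **background** is estimated as the per-pixel temporal
median of a strided subsample of frames (≥25 required): transits are sparse
in time, so the median recovers the static illumination field including its
low-order gradient and the channel walls. Each frame is then processed as:
absolute difference to background → Gaussian smoothing (σ = 1 px) → global
Otsu threshold with a floor at 8% of dynamic range (or a fixed override) →
morphological closing (3×3 disc) and hole filling → connected components →
discard components with equivalent diameter below 7 µm (debris; far below
the ≈16 µm lower gate so the filter cannot bias gated populations) or
declare the frame blank when almost no pixel rises above the floor. Blobs
with equivalent diameter above 20 µm — just above the channel height, so no
single confined object can produce them while any merge of two gateable
cells must — are split on the distance-map watershed; blobs a single object
could produce are never split, so elongated cells cannot be cut in two. A
contact train the watershed cannot separate (a cell nose resting on a flat
rear leaves no distance-map basin) is divided at the half-area plane normal
to the flow: the halves keep both members trackable and make the frame
count as multi-cell for the coincidence rule, while their cut-edge shapes
never reach DI summaries.

The single most consequential choice is the contour estimator. Pixel-edge
perimeters overestimate a disk's perimeter by up to ~27%, which alone would
produce a spurious $DI$ of ~0.1 on perfect spheres — four times the entire
error budget. Each surviving component is therefore measured on a
**subpixel closed contour** (marching-squares linear interpolation, via
`contourLines`): area by the shoelace formula, perimeter by polygonal arc
length, centroid by polygon first moments. By default the contour is the
half-amplitude iso-level of the *difference image* smoothed at only
σ = 0.6 px and restricted to the component's neighbourhood: an iso-level
on a smoothed edge shifts inward by $\sim\kappa\sigma^2/2$ (κ the boundary
curvature), so contouring a re-smoothed binary mask (available as
`contourSource = "mask"`) incurs that curvature bias twice and
measurably flattens high-curvature bullet features, while too little
smoothing lets sensor noise inflate the perimeter; σ = 0.6 on the
difference balances the two so that bullet DI bias and disk DI noise are
both small against the 0.024 error budget. Components touching the image
border are measured but flagged and excluded from summaries (their shape is
truncated). The calibration contract for this estimator is the bead bound
discussed below.

The filter chain is a reconstruction of standard practice, not a copy of
any particular laboratory's unpublished chain; users should treat the
specific filters as package design, with the bead calibration as the
objective contract they must satisfy.

## Tracking and per-cell rules

Observations are linked frame-to-frame by greedy nearest-neighbour
assignment gated to non-negative x displacement (one-pixel noise tolerance)
below $2 \times$ the nominal velocity; the neighbour distance is measured
against each track's ballistic prediction (last position plus its
estimated per-frame displacement, initialised at the nominal velocity),
since matching against the raw last position seeds identity swaps in cell
trains whenever one member drops a frame; ties resolve by area difference,
then ID. New IDs are minted only in the upstream quarter of the ROI — a
cell is tagged when it first appears — so segmentation flicker cannot
create phantom mid-channel cells; tracks tolerate up to 2 missed frames.
At the analysed occupancy (of order one cell in the test section) greedy
assignment is sufficient and auditable; global assignment would add
complexity without changing the crowded cases, which are removed anyway:

* **Coincidence rule.** Any frame on which two or more tracks are inside
  the test section is excluded from every DI summary on all involved
  tracks (hydrodynamic interaction). A track with a gap counts as present
  at its interpolated position: when two cells come close enough that
  segmentation merges them into one blob, one track loses its observation
  on exactly the frames the rule must catch.
* **Doublet/consistency guards.** Observations whose area departs from the
  track median by >40% are flagged (merged blobs, gross
  mis-segmentations — the analogue of doublet exclusion in flow
  cytometry), and tracks whose overall area range exceeds 30% of the
  median are rejected wholesale (`unstable_area`): a progressively
  overtaking neighbour contaminates even the pre-entry reference, so no
  per-frame filter can save the track.
* A cell is **accepted** only if its track entered and exited the ROI with
  at least one usable pre-entry observation and one usable non-coincident
  in-section observation; every rejection carries a reason
  (`invalid_track`, `no_preentry`, `no_insection`, `coincidence`,
  `unstable_area`). Cells whose transit is only partially recorded are
  rejected rather than silently summarised. The accept/reject ledger is the
  pipeline's primary QC surface.

$D_c$ deliberately averages *all* usable pre-entry areas rather than one
frame, suppressing single-frame segmentation noise; in-section frames can
never influence $D_c$, and pre-entry frames can never influence $DI_{max}$.

## Population statistics

`mannWhitneyOneTailed()` wraps the standard rank-sum machinery: exact
enumeration when $n_1 n_2 \le 400$ and tie-free, otherwise the normal
approximation with tie and continuity corrections. For **dose-response**
analysis a change in either direction must be caught while preserving the
one-tailed convention: each dose runs both one-tailed tests against the
untreated control, the more significant tail wins, and the pair is
Bonferroni-corrected (each tail judged at $\alpha/2 = 0.005$). $C_{min}$ is
the smallest dose that passes; the winning tail labels the response
"DI increases (softening)" or "DI decreases (stiffening)". The pattern over
doses at and above $C_{min}$ — Monotonic increase/decrease, No change,
Non-monotonic — comes from the same paired test between successive doses;
the successive-medians construction is a quantitative stand-in for a
qualitative published classification. No correction is applied *across*
cell-line pairs in multi-line panels (raw pairwise tiers are reported);
the within-pair Bonferroni is the only correction, which keeps the
four-dose global null at a familywise type-I rate ≤ 0.04.

Pressure response is an ordinary least-squares fit of gated mean DI on
driving pressure (means for the pressure trend, medians for boxplots; both
are emitted). Scatter summaries use a 2-D Gaussian KDE with Scott's
bandwidth ($\hat\sigma n^{-1/6}$ per axis) contoured at 50% of peak
density. Boxplots report median, quartiles and the 10th/90th percentiles
(type-7 interpolated quantiles — no convention was inherited, so the most
common one is used and stated), warning below $n=100$. Manifold QC passes
when per-channel mean bead velocities deviate from the grand mean by at
most 3%.

## The synthetic generator

Because no experimental recordings are distributed, every stage is
validated against a ground-truthed renderer:

* **Arrivals** are Poisson (default 100 cells/s, the reference
  throughput) with hard-core exclusion: solid cells in single-file confined
  flow cannot interpenetrate, so a trailing arrival is delayed until it
  stays at least in point contact with its leader throughout the ROI,
  including worst-case catch-up from velocity jitter. Co-transits of the
  test section still occur naturally; overlapping projections do not.
  Diameters are truncated-Normal (cells: mean 17 µm, 5% CV, chosen to
  centre the confinement gate; beads: the manufacturer's 15.13 µm, 6% CV);
  per-cell $DI_{max}$ is log-normal (default median 0.10, log-σ 0.35,
  matching the order of gated deformability distributions); velocities are
  0.3 m/s with 2% per-cell jitter.
* **Planted profile.** Each cell's ground-truth $DI(x)$ is 0 for $x<0$,
  jumps to $0.45\,DI_{max}$ at the entrance, rises linearly to $DI_{max}$
  at $x = 0.85L$, holds to the exit, then relaxes exponentially with a
  60 µm length constant. The jump, peak position and plateau reproduce the
  qualitative transit trajectory (entrance jump, gradual rise, maximum
  before exit, relaxation); the relaxation constant is a fixture parameter,
  not a physical claim — no stress/strain physics is simulated, and the
  deformation is planted, not derived from pressure.
* **Shapes** realising a given DI come from a bullet family: circular
  front cap, straight body, rear semi-ellipse that flattens as the body
  elongates. One parameter $t\in[0,10]$ morphs a circle ($t=0$, $DI=0$)
  monotonically up to $DI \approx 0.34$; `makeShape()` root-finds $t$ so
  the *polygon's own* shoelace-area/arc-length DI hits the target within
  $10^{-3}$ at exactly the requested area, and infeasible targets fail
  loudly. Projected area is held constant through the transit (the
  deformation is approximately area-preserving in projection).
* **Rendering**: 16-bit frames, background level 30 000 with a ~3%
  illumination tilt, dark walls along the test section, cells attenuate
  35% of background (trypan-blue-like contrast), additive Gaussian noise
  with σ = 2% of the dynamic range, no motion blur (1 µs exposure
  assumption). Polygons are rasterised by a compiled scanline fill, exact
  along x with 4× supersampling along y, so renderer artifacts stay well
  below the boundary-discretisation error being studied. All randomness
  derives from one seed; per-frame noise streams are keyed by frame index,
  so rendering any subset of frames is bit-identical to rendering the
  whole stack and long recordings can be processed in bounded memory.
* The **event table** (`emitEventTable()`) bypasses rendering entirely:
  per (cell, frame) rows carry the planted polygon's exact area, perimeter
  and DI, so the statistics layer can be tested with zero imaging error.

What the generator does *not* emulate — debris, out-of-focus cells,
asymmetric illumination flicker, cell rotation, shape irregularity, wall
adhesion — bounds what passing tests show about real data: they validate
the measurement and statistics chain, not robustness to every acquisition
pathology.

## Calibration and validation contracts

* A perfect disk has $DI=0$; the polygon estimator on an inscribed regular
  $n$-gon reproduces the closed form $\pi^2/(6n^2)$ (so a 256-gon measures
  $2.5\times10^{-5}$, and refinement drives DI below $10^{-6}$).
* **Bead bound.** ≥500 rendered rigid beads, processed by the full
  pipeline and gated to single particles ($D_c/D_h < 0.95$), must show
  maximum measured DI ≤ 0.024 — the bead-derived error bound that real
  measurements quote as their DI resolution. This is the contract that
  forces the subpixel contour estimator.
* End-to-end parameter recovery: over 10 seeds at 200 cells/sample, the
  recovered median $DI_{max}$ is within 0.01 and the median $D_c$ within
  0.5 µm of the planted values.
* Tracking fidelity: ≥99% one-to-one ground-truth/track correspondence at
  the default arrival rate; coincidence flags match ground-truth test
  section co-occupancy exactly, except on frames where a true centroid
  lies within one pixel of an entrance/exit plane (at the measurement
  resolution, in/out is genuinely undecidable there).
* $C_{min}$ recovery: with an effect planted at and above the second of
  four doses, $C_{min}$ lands on that dose in ≥95% of replicates, and the
  global null yields $C_{min}$ = none with familywise type-I ≤ 0.05.

## Problem sizes and numerical choices

The validation suite renders its recordings at a 48-row sensor crop (the
channel, walls and cell envelope span well under 47 µm) and 360-440
columns, with arrival rates of 300-400 cells/s for the large bead and
recovery runs; these sizes keep a full validation pass desk-scale while
preserving the optical scale (0.97 µm/px), frame rate, noise and velocity
regime of the reference setup. Tiny negative DI values (≥ −10⁻⁹) arising
from subpixel contour noise on near-perfect disks are clamped to zero;
larger isoperimetric violations raise errors, since they indicate
estimator bugs rather than noise. Root-finding tolerances are 10⁻¹² on the
shape parameter; DI(x) profile bins default to 10 µm with a centred
3-point moving average (bin-mean-then-smooth, matching curves whose points
are per-bin means over ≥52 cells; smoothing over per-frame sequences is a
noted alternative).

## Known limitations

* The filter chain and linking algorithm are reconstructions; only their
  calibration contracts are anchored to published numbers.
* No elastic modulus or relaxation-time inversion: DI is reported as-is.
* Greedy linking assumes dilute transits; at sustained test-section
  occupancy ≫1 the coincidence rule discards most frames and throughput
  collapses by design.
* The renderer's constant-projected-area assumption and bullet family are
  idealisations; real cells show richer contours and area changes, which
  the area-consistency guards must then be tuned against.
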