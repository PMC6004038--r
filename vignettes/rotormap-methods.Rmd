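---
title: "Methods: detecting and measuring re-entry cores in monolayer optical maps"
author: "rotormap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and measuring re-entry cores in monolayer optical maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cultured cardiomyocyte monolayers with slow conduction (tens of mm/s, an
order of magnitude below working myocardium) spontaneously exhibit two kinds
of activity visible in calcium- or voltage-sensitive fluorescence movies:
*triggers* — cells or small clusters with automaticity that fire wavefronts
at low, irregular rates — and *re-entry* — a wavefront circulating
repeatedly around a core of conduction block at a stable rate of roughly
1.4–3.3 Hz. At microscopic resolution the core of such re-entry is not the
round, featureless area that classical functional re-entry theory assumes;
it resolves into thin lines of conduction block, sometimes connected to
small patches of cells. `rotormap` implements the full analysis chain for
this kind of data — activation mapping, wavefront counting and
classification, trigger localization, conduction-delay core detection,
morphology classification, convex-hull perimetry, dominant frequency,
dual-channel concordance, and the study-level statistics — together with a
ground-truthed synthetic-monolayer generator that the entire chain is
validated against.

## Activation detection

Activation time is the point of steepest upstroke of the fluorescence
signal. Traces are kept unfiltered for display and normalization, but the
derivative used for detection is lightly smoothed (3-frame moving average by
default): differentiating raw shot noise at 100 fps makes steepest-upstroke
detection unusable, while a 30 ms window is short against any transient of
interest. An event requires a local rise of at least `prominence` (default
0.2) of the trace's dynamic range, and consecutive events must be separated
by `refractory_ms` (default 100 ms — comfortably below the fastest rotor
period of interest, ~300 ms, so genuine 3.3 Hz activity is never
suppressed, while noisy upstrokes are not double-counted). Ties within a
constant-slope run resolve to the earliest frame. A trace whose dynamic
range falls below `silent_range_frac` (default 0.3) of the movie-wide
robust range is silent: this is what lets a truly inactive core cell report
*zero* events rather than noise-triggered ones.

Activation maps apply the same rule per pixel inside one cycle-length
window, vectorized across the frame; pixels failing the prominence gate are
missing (`NA`). The per-pixel implementation and the vectorized one are the
same computation and the tests hold them to each other.

## Dominant frequency

The dominant frequency (DF) of a trace is the largest peak of its
zero-padded periodogram inside a search band (default 0.5–10 Hz), with the
spectral resolution 1/duration reported alongside. For a *recording*, DF is
the median over a grid of per-pixel estimates rather than the DF of the
field-mean trace: a rotor's activation phases tile the whole cycle, so the
spatial mean largely cancels its own fundamental and its residual spectrum
can peak on a harmonic. The per-pixel median is immune to this and its
consistency across pixels doubles as the periodicity test used to decide
between per-cycle and burst-wise wavefront segmentation.

## Wavefront segmentation and classification

Activation events are pooled on a coarse ROI grid (default 8 px blocks).
Two regimes:

* **Strongly periodic recordings** (sharp, mutually consistent per-pixel
  spectral peaks, at least five cycles): one wavefront per cycle. Arrival
  times are read at the most active ROI (the reference point) and each
  cycle's propagation direction is the plane-fit gradient of that cycle's
  ROI activation map. Slicing a rotor's continuous phase field with
  watershed would necessarily cut it at an arbitrary phase each cycle; the
  per-cycle treatment avoids that.
* **Irregular recordings**: events are grouped into bursts separated by
  quiescent gaps, and each burst's activation-time surface is split by
  watershed into basins, one wavefront each — which is what keeps two focal
  sources whose waves collide mid-field as two wavefronts. A later basin
  whose *origin* touches an earlier basin with matching activation times is
  a continuation of the same wave (e.g. a wave flowing around an obstacle)
  and is merged back; head-on collisions meet at their latest points, never
  at an origin, and stay split.

A recording is classified re-entrant when at least five consecutive
wavefronts (the "over four" rule) are very regular: pairwise directions
within 30° and an inter-wave interval CV of at most 0.15. The study this
emulates gives no numbers for "very regular"; these defaults cleanly
separate driven rotors (interval CV below 0.05 in the synthetic data) from
trigger activity with cycle-length CV 0.3, and both are exposed in
`reentry_config()`. Trigger counting follows the surrogate convention:
counts of distinct wavefront origins, merged within `match_tolerance_um`
(default 100 µm, a few cell diameters), with origin positions refined to
the first-frame activation disc on the pixel-level map. The refinement halo
scales with the measured wave speed because at 100 fps a 41 mm/s wavefront
travels 41 px of a 10 µm/px field per frame — the first-frame disc, not any
single pixel, is the origin's true footprint.

## Conduction-delay core detection

The core detector asks where pixels in close spatial proximity activate far
apart in time. All activation-time differences are circular: they are taken
modulo the rotor period and folded onto `[0, period/2]`, so two pixels on
opposite sides of a block line — activating half a cycle apart — score
~period/2 regardless of which cycle index either activation fell into,
while the arbitrary wrap line of a single-cycle map scores ~0. This also
makes period normalization explicit: the same geometric core scores the
same fraction of its own cycle whatever the rotor's rate.

Scores aggregate as the per-neighbour-pair *median across cycles* (robust
to one bad cycle) and then the *maximum over neighbours* within
`delay_radius` (default 3 px — about a cell diameter at the default
binning), which is sensitive to any persistently discordant direction. The
exported heatmap carries this radius-3 score plus an 8-adjacent
("sharp") layer used for delineation: the radius-r band is by construction
a band of width ~2r around the block, whereas the immediate lining of the
interface is what the core mask should be.

Segmentation thresholds the sharp layer at `block_threshold` (default 0.25)
of the period, then adds never-active pixel groups whose active boundary
spans at least that threshold in circular delay — a silent region whose
surroundings are out of phase is conduction block, which is exactly what
the observed cores are (inactive cells, or cells with calcium transients
but no propagated action potential). Components touching the image border
or covering more than a fifth of the field are never added (unobserved or
unactivated tissue, not block). A one-pixel morphological closing bridges
noise gaps and either the largest or all qualifying components are kept.

## Morphology and perimetry

The core mask is thinned to a one-pixel skeleton (iterative two-pass
thinning) and classified by two quantities: the number of skeleton
endpoints and the thickness ratio — mask area over skeleton length times
the expected width of a thin block line (two cell diameters). Thin
two-ended masks are `single_line`, thin masks with three or more endpoints
`multi_line`, and anything substantially thicker than a line
`lines_plus_area`. Masks under 3 px are indeterminate.

The perimeter is the convex hull of the mask's pixel centres — the smallest
convex polygon containing the core, hence the shortest path around it —
reported in mm. Hull on pixel centres (not outer pixel boundaries) keeps
the measure determinate; collinear (degenerate) masks return exactly twice
their span, out and back along the line. Dual-channel agreement between
voltage- and calcium-derived masks is quantified by the Dice coefficient.

## The synthetic monolayer

The generator is phenomenological by design: the analyses only consume
event timing and propagation geometry, so an event-based
threshold/refractory lattice with exact ground truth serves better than an
ionic model. Its components:

* **Cell lattice.** Poisson-disc centroids (mean diameter 25 µm) on a
  colony disc — the study's colony areas 3.5, 6.4 and 9.8 mm² are the
  defaults — with territories and the coupling graph from a discrete
  (raster) Voronoi tessellation. A configurable number of cells is
  automatic, firing at a mean cycle of 1.5 s with CV 0.3; the source study
  describes trigger rates only as "low and irregular", so these two
  numbers are fixture choices, not measured values.
* **Dynamics.** A cell fires when excitable and either its jittered
  automatic timer elapses or the coupling-weighted input from neighbours
  that fired one conduction latency earlier reaches its threshold within a
  5 ms integration window. Latency is distance over a conduction speed;
  with the default threshold (0.15 of total neighbour weight) the emergent
  planar velocity equals the link speed, so the 41 mm/s default reproduces
  the cell line's known conduction velocity directly. Input arriving in
  the last 60 ms of a cell's refractory period is held and re-applied at
  recovery — post-repolarization waiting, the ingredient that lets a
  circulating head ride a recovering tail.
* **Block structures.** Lines, lines with a cell patch, or three to four
  connected lines: coupling is cut across every branch, patch cells become
  inexcitable, and cells within 100 µm of the structure conduct 8× slower
  with a shorter (250 ms) refractory period. Re-entry, when a recording
  must contain it, is *driven*: the margin cells are stimulated in
  rotational phase order at the target period, with the core loop
  coupling-isolated from the bulk except at one emission port. Sustained
  emergent re-entry is not attainable in this model class — the fast bulk
  recaptures the colony synchronously each lap and reinvades whichever
  core arc has recovered, extinguishing the head — and the package does
  not pretend otherwise; what the analysis sees (regular rotational
  wavefronts at fixed period, half-cycle delays across the block, 1:1
  colony capture through the port) is genuine simulated propagation, with
  only the initiation imposed. This mirrors the observation that core
  cells activate but do not transmit.
* **Rotor phantoms.** For controlled core-detection studies the rotor is
  analytic: phase winds once about the structure centroid, plus a
  per-branch antisymmetric "sideness" term (±0.175 cycles per side)
  attenuated laterally over 10 px and notched off ~1.5 px past each branch
  tip. The result is an activation-time jump of 0.35 cycles across every
  branch along its full length, isochrones terminating on the block, no
  spurious jump anywhere else, and ground truth known to the pixel: the
  true core is the one-pixel lining of pixels whose 8-neighbourhood
  straddles a branch, plus patch pixels. Core-lining cells are rendered
  per mode: sub-threshold random fluctuations (default), silent, or firing
  at twice the rotor rate (driven alternately from both sides). A
  physically tapered phase construction (conformal slit map) was
  considered and rejected: its cross-line delay vanishes toward the line
  tips, which no thresholded detector can reconcile with pixel-accurate
  tip recovery.
* **Fluorescence.** Each event contributes a stereotyped transient
  (calcium: 20 ms rise, 150 ms decay; voltage: 5 ms, 50 ms), the calcium
  channel trails the voltage channel by a configurable lag (default 3
  frames = 30 ms at 100 fps), photobleaching is a multiplicative
  exponential, noise is additive Gaussian, and frames quantize to 16 bits.
  In dual-channel phantoms a one-pixel margin of cells around the core
  shows calcium transients but no action-potential upstroke, reproducing
  the observed asymmetry in which the voltage-derived core is the larger.

What the generator does **not** emulate: motion, uneven staining,
photon-physics noise (noise here is white and Gaussian), cell-scale
heterogeneity of transient shape, fibroblast-mediated coupling, and — per
the above — spontaneous re-entry initiation. Passing the validation
batteries therefore demonstrates correctness of the measurement chain on
idealized recordings with known truth, not robustness to every artefact of
real microscopy.

## Numerical choices and degenerate inputs

* Time quantization is one frame (10 ms); activation-time agreement with
  ground truth is asserted to 2 frames (detection sits on the steepest
  point of a 20 ms rise, ~1 frame after the event).
* Periodic-kernel lookups use a 1 ms table; rasterization places structure
  centres off the pixel lattice (fixed fractional offsets) so branch lines
  never pass exactly through pixel centres.
* Constant traces normalize to zeros with a silent flag rather than
  raising; quiescent movies raise a "no activity" error only where a
  result would otherwise be fabricated (activation maps, delay maps).
* Single-pixel masks are indeterminate for perimetry; sub-3-px masks for
  morphology. Degenerate contingency tables (a zero margin) return p = 1
  with a flag.
* Mann-Whitney uses the exact null only without ties and with both groups
  of size ≤ 8, matching the enumeration oracle exactly; otherwise the
  tie-corrected normal approximation. The KS normality screen estimates
  mean and SD from the sample and carries the resulting conservativeness
  as an explicit caveat flag.
* Two-sided Fisher tests sum hypergeometric point probabilities no larger
  than the observed table's; this is the convention under which the
  printed contingency (6/16 vs 1/25 re-entry, three comparisons)
  reproduces p = .028. A doubling convention does not reproduce it.

## Validation batteries and problem sizes

The acceptance script and the test suite run the same seeded studies,
sized to complete in a few minutes on one CPU: 20 rotor phantoms at
256×256 px (3 s at 100 fps, noise 5%) with 20 planar-wave controls at
200×200 for core localization; DF recovery across 1.4–3.3 Hz on 10 s
noise-free traces; up to 20-wave planar trains at 160×160 for counting;
20 five-rotor families at 96×96 for the perimeter-frequency direction;
exhaustive Fisher enumeration to table total 14 plus 300 random tables to
total 40; and a 200-pair site-level stability experiment. The colony-size
experiment in `analysis/05` runs at reduced areas (0.6–1.5 mm²) and 8 s
recordings: the experiment's logic — per-recording simulation, analysis,
exclusion of trigger counts under re-entry, Fisher/Mann-Whitney chains —
is identical at any scale, and the study-size areas remain the defaults
of `run_colony_size_experiment()`.

## Known limitations

* The lattice cannot initiate re-entry on its own (driven rotation only);
  induction dynamics are out of scope.
* The wavefront counter's periodic path reports one wavefront per cycle;
  two independent sources locked to the same rhythm would be undercounted
  (not a configuration the generator produces).
* Channel-lag estimates carry a ~1-frame kernel-shape bias (the calcium
  upstroke is intrinsically slower than the voltage upstroke), which is
  why a 3-frame imposed lag may read as 4; the acceptance band (±1 frame)
  reflects this.
* Hull perimetry on pixel centres understates a rasterized disc's
  perimeter by up to ~1%; the analytic-disc tolerance (3%) absorbs
  rasterization both ways.
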