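# rotormap

Analysis of re-entry (rotational activity) in optical-mapping recordings of
cardiomyocyte monolayers, with a ground-truthed synthetic-monolayer
generator used to validate every step.

Slowly conducting monolayers (HL-1–derived lines and similar preparations,
~41 mm/s) show two kinds of spontaneous activity in calcium- or
voltage-sensitive fluorescence movies: focal **triggers** firing wavefronts
at low, irregular rates, and **re-entry** — a wavefront circulating at
1.4–3.3 Hz around a core of conduction block that, at microscopic
resolution, is made of thin lines and small patches of cells rather than a
round area. The package is aimed at researchers analysing such recordings
(or building analysis methods for them) and implements:

- **Activation mapping** — per-pixel activation time at the point of
  steepest fluorescence upstroke; per-cycle isochronal maps.
- **Wavefront analysis** — segmentation (per-cycle for strongly periodic
  recordings, watershed-over-bursts otherwise), counting, propagation
  direction, and the re-entry rule: *more than four* consecutive wavefronts
  with consistent direction (≤ 30°) and regular intervals (CV ≤ 0.15).
- **Trigger localization** — wavefront origins refined to the first-frame
  activation disc, merged into sites, with pre/post location matching
  (`same_location` / `other_location` / `no_activity`).
- **Conduction-block core detection** — for pixels in close proximity, the
  circular activation-time difference (mod the rotor period, folded to
  half a period) aggregated as per-cycle median then max over neighbours;
  thresholding at a fraction of the cycle plus inclusion of silent regions
  whose surroundings are out of phase yields the core mask.
- **Core geometry** — skeleton-based morphology classes (`single_line`,
  `lines_plus_area`, `multi_line`) and convex-hull perimetry in mm.
- **Dominant frequency** — zero-padded periodogram per trace; per-pixel
  median for recordings.
- **Dual-channel concordance** — voltage-to-calcium frame lag by
  cross-correlating smoothed derivatives; Dice agreement of
  channel-specific cores.
- **Statistics** — two-sided Fisher exact tests (point-probability
  convention) with Bonferroni correction, Mann-Whitney with
  Dunn–Bonferroni adjustment, Kolmogorov–Smirnov normality screening, OLS
  regression.
- **Synthetic monolayers** — an excitable cell lattice (Poisson-disc
  cells, raster-Voronoi coupling, threshold/refractory dynamics with
  conduction latency, calibrated 41 mm/s planar velocity) plus analytic
  rotor/planar/focal phantoms with pixel-exact ground truth, rendered to
  16-bit fluorescence movies with configurable noise, photobleaching and a
  voltage-to-calcium lag (default 3 frames).

## Worked example

A rotor phantom circulating around a 400 µm line of block, analysed blind:

```r
library(rotormap)

core <- core_structure("line", center = c(128, 128), angle_deg = 25,
                       length_px = 40)                  # 10 um/px
ph <- make_rotor_phantom(core, period_ms = 345, dim = c(256, 256),
                         duration_s = 3, noise_sd = 0.05, seed = 4)
cg <- detect_core(ph$movie, reentry_config(df_band_hz = c(1, 10)))

cg$dominant_frequency_hz   # 2.917  (truth: 1000/345 = 2.899 Hz)
cg$morphology              # "single_line"
cg$perimeter_mm            # 0.826  (~2 x 40 px x 10 um, out and back)
mask_iou(cg$mask, ph$truth$core_mask)        # 1
mask_hausdorff(cg$mask, ph$truth$core_mask)  # 0 px
```

The detector recovered the rotor rate to the spectral resolution, classified
the core as a single line, measured its hull perimeter, and reproduced the
true core mask pixel for pixel on this seed (IoU across a 20-phantom battery
ranges 0.87-1.00; see `scripts/acceptance.R`).

The numbered drivers under `analysis/` run the package end to end and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate_recordings.R   # exemplar recordings + ground truth
Rscript analysis/02_activation_mapping.R    # wavefronts, classification, triggers
Rscript analysis/03_core_geometry.R         # cores, morphology, perimetry
Rscript analysis/04_dual_channel.R          # voltage/calcium concordance
Rscript analysis/05_statistics.R            # contingency, experiments, regression
```

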