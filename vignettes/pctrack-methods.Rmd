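---
title: "Methods: how pctrack quantifies photo-conversion time-lapse data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how pctrack quantifies photo-conversion time-lapse data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The experiment and its data

A photo-conversion (PC) experiment labels a subpopulation of a
photoconvertible fluorescent protein (e.g. Dendra2) by switching its
emission from green to red with a short UV pulse aimed at a small
cellular region, then follows the red form through a time series. The
data is a multi-page grayscale TIFF: a green channel imaging the whole
cell (acquired pre-conversion and throughout), and a red channel that is
essentially empty before the pulse and afterwards carries the converted
protein as it diffuses, relocalizes and bleaches.

`pctrack` assumes a single cell per field, fixed stage and focus (no
registration is performed), and one conversion event at the start of the
red series. These match the acquisition style the method was designed
for; violations (drift, multiple cells, repeated pulses) are out of
scope.

# Channel separation

Acquisition software does not always preserve channel metadata in
exported TIFFs, so `split_channels()` recovers the channels
statistically. Frames are partitioned into two streams by `layout`:

* `interleaved` — alternating frames,
* `blocked` — first half vs second half,
* `auto` (default) — whichever of the two layouts yields the larger
  ratio of stream-mean variances.

Per-frame *population* variance is used (the definition is a choice; the
divisor is immaterial at these pixel counts), and the stream with the
higher mean variance is labeled green, because the green channel images
the full cellular signal while the red stream starts near-empty.
Assignment is per stream, not per frame, so late red frames that become
bright after conversion cannot flip their stream. If the two stream
means differ by less than 1% (`tie_ratio = 1.01`) the split is reported
as ambiguous and refused: real pre-conversion red frames are nearly
empty, so genuine data sits far from this tie.

# Red-channel preprocessing

Four stages, each kept in the returned record for inspection:

1. **3×3 median filter** per frame, removing spatial shot noise while
   preserving edges. Borders are handled by edge replication; zero
   padding would darken the image rim and bias border statistics.
2. **Background subtraction.** The first red frame is acquired before
   the pulse and images only background (autofluorescence, offset,
   bleed-through). It is subtracted from every frame; negative
   differences are clamped to 0, since negative fluorescence is not
   physical and would break the unit-interval interpretation of the
   later stretch.
3. **Temporal Gaussian smoothing.** Each pixel's time series is
   convolved with raw samples of the Gaussian density at integer frame
   offsets (default σ = 1 frame, width 5, i.e. weights ≈
   [0.054, 0.242, 0.399, 0.242, 0.054]). At every frame — interior and
   boundary — the weights actually covering existing frames are
   renormalized by their own sum. This has two consequences chosen
   deliberately: a constant series passes through exactly (the raw mask
   sums to 0.988, so un-normalized smoothing would dim every frame by
   about 1.2%), and the filter is curtailed at the sequence ends by
   truncation rather than padding.
4. **Sequence-wide contrast stretch** `(I − I_min)/(I_max − I_min)` with
   the extrema taken over all pixels of all frames, mapping the sequence
   onto [0, 1]. Stretching per frame instead would fabricate apparent
   temporal intensity changes. A constant sequence has no range and
   raises a degenerate-range error.

**Why subtraction precedes smoothing.** The conversion onset is a step
in time; a temporal Gaussian smears it across its half-width. If the
reference frame were smoothed before being subtracted, it would already
contain leaked post-conversion signal, and subtracting it would cancel a
substantial part of the early converted signal. Because the renormalized
smoother preserves constants, subtracting first is mathematically
identical to smoothing first and subtracting the *unsmoothed* reference
— which is what "the pre-conversion frame is the background" means. The
onset smear itself is unavoidable: the first `(width−1)/2` post-
conversion frames are pulled toward the empty reference frame, which is
why decay measurements (below) start beyond that transient.

All processing is in double precision regardless of the storage dtype;
conversion happens once at ingest. The green stack is used only for
channel classification and is never preprocessed.

# The statistical model and cell segmentation

The mean image `M(x,y)` and the population standard-deviation image
`S(x,y)` (divisor N, so a single-frame stack yields S ≡ 0 rather than an
error) summarize the processed sequence: `M` is a noise-reduced picture
of the cell, `S` highlights where the converted protein actually moved.

The cell region is `S > mean(S) + sd(S)` — strict inequality, so a
uniform `S` yields an empty mask (reported, not an error) and equality
goes to background; the population SD over all pixels is used. The
thresholded mask is cleaned by morphological opening with a disk of
radius 1 (a 3×3-scale element), removing isolated speckle while leaving
any structure at least as large as the element. Note this mask covers
the *high-temporal-variation* region, which for a sparse converted blob
can be considerably smaller than the anatomical cell.

# Migration-map classification

Each in-cell pixel trajectory is summarized by the early-window mean E,
the late-window mean L (windows of `ceil(early_fraction × N)` frames,
default `early_fraction = 0.1`), and its overall temporal mean. Classes,
in priority order:

* **accumulation** — sustained extreme brightness: L at or above the
  0.99 quantile (`bright_quantile`) of in-cell temporal means, or L ≥
  `sat_threshold` (0.95, unit scale). Requiring the *late* window to be
  extreme is the package's deliberate reading of "extreme brightness
  indicates accumulation": a pixel a bright blob merely passes through
  is transiently extreme but dims again, and labeling it accumulation
  would mark accumulation in every experiment — including a freely
  diffusing protein, where the accumulation class must be empty.
* **injection** — bright but dimming: E ≥ `bright_floor` (0.2) and
  L ≤ (1 − `delta`)·E, default `delta = 0.2` (a 20% endpoint contrast).
* **diffusion toward** — the mirror image: L ≥ `bright_floor` and
  E ≤ (1 − `delta`)·L.
* **background** — outside the mask, or in-cell with temporal SD below
  `dark_sd_factor` (0.5) times the segmentation threshold ("relatively
  dark with minimal variation"; with a mask from `segment_cell()` this
  in-cell rule is usually vacuous).
* **unclassified** — everything else.

Endpoint-window contrast is the simplest faithful formalization of
"bright but dims" / "dim becoming bright"; every threshold is exposed.
The `delta` and quantile rules are scale-free; `bright_floor` and
`sat_threshold` are absolute on the unit scale, and since the data is
already normalized, `sat_threshold` flags sequence-scale maxima rather
than true sensor saturation.

The conversion point is the centroid (rounded) of the largest
8-connected injection component; if rounding lands outside a non-convex
component, the nearest component pixel is used, so the estimate always
lies in the injection region. Component connectivity is 8-neighborhood
throughout.

# ROI growth and tracking

Seeds are given as (row, col) coordinates (scriptable, unlike a mouse
click) and grown on the mean image `M` by classic Adams–Bischof seeded
region growing: the 8-connected boundary of the region is maintained and
the boundary pixel whose intensity is closest to the *running* region
mean is admitted, updating the mean after each admission, until the best
candidate deviates by more than `tolerance` (default 0.1 in unit-scale
intensity) or the region reaches `cap` pixels (default 250; at most 10
regions by default). Ties are broken toward the lowest (row, col)
lexicographically, so growth is deterministic; the admission sequence
does not depend on `tolerance`, which yields nested regions for nested
tolerances. `fixed_area_roi()` provides the naive fixed-disk comparator,
which unlike seeded growth leaks into surrounding compartments whenever
its radius exceeds the structure.

Traces are measured on the processed stack: per-ROI mean, background
mean (pixels outside the cell mask), and total in-mask fluorescence per
frame. The pre-conversion red frame is excluded from tracking — after
background subtraction it is identically zero, so it carries no signal
and would make ratios against the total undefined.

**Photobleaching.** The net drop in total fluorescence is reported as a
signed percentage, `100·(T₁ − T_end)/T₁`. The pipeline computes it on
the *median-filtered, unstretched* stack: stretching rescales and
shifts totals arbitrarily, and the smoothing transient biases the first
frames. Correction multiplies each ROI trace by `T₁/T_t` — normalizing
against total cellular fluorescence — anchored to the first tracked
frame so corrected traces keep raw units. On a global multiplicative
decay this inversion is exact. When decay is *measured* from traces, the
measurement starts `(width−1)/2` frames after conversion to clear the
smoothing transient.

# The synthetic-data generator

`generate_fixture()` builds ground-truthed experiments: a static green
cell image (elliptical cell, nucleus, small disk compartment; intensity
levels 0.35 / 0.55 / 0.75 plus a 0.05 floor); a red channel with an
empty pre-conversion frame, then a Gaussian blob of fixed total mass
spreading with variance `r₀² + 2Dt` (analytic diffusion rather than a
stochastic PDE — closed-form truth enables exact assertions), confined
to the cell by renormalized clipping so mass is conserved; optional
per-frame transfer of a fraction of the free mass into the compartment;
exponential bleaching `e^(−kt)`; Gaussian read noise (sd 0.005) with
optional Poisson shot noise. Defaults: 128×128 pixels, 100 frames per
channel, interleaved, blob σ₀ = 4 px with peak 0.8, D = 1.5 px²/frame,
k = 0.00165/frame — a rate that loses roughly 15% of total fluorescence
over the series, the magnitude typical of real spinning-disk PC
acquisitions. The truth record defines the conversion spot as the 1/e²
disk of the initial Gaussian (radius 2σ₀), the standard laser-spot
extent.

What the simulator does *not* emulate: photophysics (blinking,
conversion efficiency), 3-D sectioning, stage drift, multiple cells,
structured backgrounds, or detector gain beyond Poisson/Gaussian noise.
Tests passing on fixtures therefore demonstrate algorithmic correctness
under the stated model, not robustness to every property of real
microscopy data.

# Numerical and interface choices

* TIFF dialect: 8/16-bit unsigned integer stacks round-trip losslessly;
  float stacks are stored as 32-bit samples on the unit interval
  (precision 2⁻³²). True IEEE-float TIFFs from other software are read
  as stored.
* Configuration files are YAML, the established plain-text config format
  in the R ecosystem; the resolved configuration is written next to every
  run's outputs so a run can be reproduced from its own artifact
  directory.
* The analysis pipeline is fully deterministic; randomness exists only
  in the simulator and derives from its `seed`.
* Degenerate inputs have defined behavior throughout: constant sequences
  refuse to stretch, uniform SD images give empty masks, empty injection
  classes refuse a conversion point, ambiguous channel variance refuses
  to split.
* Test problem sizes: unit tests run on images from 6×6 up to 64×64 and
  sequences of 2-40 frames; end-to-end behavioral checks use the
  default 128×128, 100-frame-per-channel simulation, which the full
  pipeline processes in a few seconds.

# Known limitations

* The high-variation (SD-threshold) mask underestimates the anatomical
  cell for sparse blobs, so the "total cellular fluorescence" is the
  total over that mask; with strong diffusion, signal moving out of the
  mask appears as extra decay in the bleach report. A diffusion-free
  measurement recovers the true bleach rate to a fraction of a
  percentage point.
* `sat_threshold` operates on normalized data and cannot distinguish
  true sensor saturation from the sequence maximum.
* ROIs are fixed pixel sets; structures that move between frames are not
  followed.
* The relation between the growth search and the size cap is exposed as
  independent parameters (`tolerance`, `cap`) rather than reconciled
  into one rule.
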