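# pctrack

Quantitative tracking of photo-converted fluorescent proteins in
dual-color live-cell time-lapse microscopy.

In a photo-conversion (PC) experiment, a green-to-red photoconvertible
protein (Dendra2 and its fusions are the classic examples) is switched in
a small cellular region by a brief UV pulse, and the red form is then
followed through a confocal time series to reveal where the tagged
protein travels and accumulates. `pctrack` turns the raw multi-page TIFF
of such an experiment into quantitative, bleach-corrected fluorescence
traces and a per-pixel map of protein movement. It is written for cell
biologists analyzing single-cell PC time-lapse data, and for method
developers who need a fully scriptable, deterministic reference pipeline
with a ground-truthed simulator.

## The method

Given an acquired sequence of frames `I(x, y, t)`:

1. **Channel separation.** Green (pre-conversion) and red
   (post-conversion) frames often share one TIFF page sequence. Frames
   are partitioned by layout (interleaved / blocked / auto-detected) and
   the stream with the higher mean per-frame variance is labeled green —
   the green channel images the full cell, while the red channel starts
   essentially empty.
2. **Preprocessing** of the red stack: a 3×3 spatial median filter per
   frame; subtraction of the pre-conversion red frame (the background);
   temporal Gaussian smoothing with the kernel
   `G(t) = exp(-t²/2σ²)/(σ√2π)` sampled at integer frame offsets (σ = 1,
   width 5 by default, i.e. weights ≈ [0.054, 0.242, 0.399, 0.242,
   0.054], renormalized over the frames actually covered); and a
   sequence-wide contrast stretch `(I − I_min)/(I_max − I_min)` so the
   global maximum is 1 and minimum 0.
3. **Statistical model.** The temporal mean image
   `M(x,y) = (1/N) Σ_t I(x,y,t)` and population standard-deviation image
   `S(x,y) = sqrt((1/N) Σ_t (I − M)²)`.
4. **Migration map.** The cell is segmented as `S > mean(S) + sd(S)`
   (strict), cleaned by morphological opening; each in-cell pixel
   trajectory is classified from its early-window mean E, late-window
   mean L and overall mean into *injection* (bright but dims),
   *diffusion toward* (dim becoming bright), *accumulation* (sustained
   extreme brightness), *background*, or *unclassified*. The conversion
   point is the centroid of the largest injection component.
5. **ROI tracking.** Regions of interest grow from user seeds on `M` by
   Adams–Bischof seeded region growing (admit the boundary pixel closest
   to the running region mean, up to a tolerance; at most 250 pixels per
   region and 10 regions by default). Mean ROI fluorescence, background
   and total in-cell fluorescence are tracked per frame; the net drop in
   total fluorescence is reported as a signed percentage, and ROI traces
   are corrected for photobleaching by normalizing against the total at
   each time point.

A ground-truthed simulator (`fixture_spec()` / `generate_fixture()`)
produces synthetic PC experiments — a diffusing Gaussian blob confined to
an elliptical cell, optional compartment accumulation, exponential
bleaching, camera noise — so every stage is testable without microscope
data.

## Worked example

Simulate a compartment-binding experiment and analyze it:

```r
library(pctrack)

spec <- fixture_spec(accumulation_rate = 0.02, seed = 42)   # 128x128, 100+100 frames
fx <- generate_fixture(spec)
write_stack(fx$stack, "demo/stack.tif", dtype = "float")

cfg <- pipeline_config("demo/stack.tif", "demo/out",
  seeds = list(pc_site = c(70, 52), nucleoplasm = c(59, 54),
               nucleolus = c(56, 76), cytoplasm = c(97, 77)))
res <- run_pipeline(cfg)
```

which logs:

```
read 200 frames of 128 x 128
channel split (interleaved): 100 green / 100 red, variance ratio 21
cell mask: 441 px above SD threshold 0.02762
migration map: accumulation=82, injection=172, diffusion_toward=0, background=15943, unclassified=187
estimated conversion point: (70, 52)
roi 'pc_site': 250 px from seed (70, 52)
roi 'nucleolus': 82 px from seed (56, 76)
photobleaching: 21.566% drop in total cell fluorescence
```

Reading the numbers: the splitter recognized the alternating green/red
layout (the green stream has 21× the red stream's variance); the 82
accumulation-labeled pixels coincide with the simulated compartment and
the 172 injection-labeled pixels with the conversion spot, whose centroid
(70, 52) is exactly the simulated conversion center; the `nucleolus` ROI
stopped at the 82-pixel compartment boundary instead of leaking into the
nucleoplasm, while ROIs seeded in homogeneous areas grew to the 250-pixel
cap. The reported drop in total masked fluorescence combines true
bleaching with signal diffusing out of the high-variation mask; on a
diffusion-free run it matches the simulated bleach rate to a fraction of
a percentage point. `demo/out/` then contains the mean/SD images, the
migration map with class counts, the traces CSV (raw trace columns are
replaced by bleach-corrected ones), the trace plot, the resolved
configuration and the run log.

The same workflow is scriptable from a shell via the thin CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pctrack.R", package="pctrack"))')" \
  run --input demo/stack.tif --out demo/out --seeds "70,52;56,76"
```

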