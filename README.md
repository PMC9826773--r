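# ctiq — task-based CT image quality for virtual monoenergetic images

`ctiq` is an R package for task-based image-quality assessment of CT
slice stacks in Hounsfield units, aimed at medical physicists comparing
reconstruction algorithms on quality-assurance phantoms. It implements
the full pipeline used to characterize spectral reconstructions on
virtual monoenergetic images (VMIs):

* **Noise power spectrum** — 2D NPS from second-order-detrended ROI
  periodograms,
  `NPS2D = ΔxΔy/(NxNy) · mean |FFT2(ROI − FIT)|²`,
  with radial rebinning, noise magnitude `√∬NPS` (HU) and the average
  spatial frequency `f_av = ∫f·NPS(f)df / ∫NPS(f)df` (noise texture).
* **Task transfer function** — circular-edge method: radial ESF around a
  circular insert, central-difference LSF, normalized Fourier modulus,
  and TTF50.
* **Iodine contrast** — `Contrast = HU_iodine − HU_solid water` from
  circular-ROI means.
* **NPWE detectability** — for a disk task `W(ρ) = CπR²|2J₁(2πRρ)/(2πRρ)|`,
  `d′² = [∬|W|²TTF²E² du dv]² / ∬|W|²TTF²·NPS·E⁴ du dv`,
  with an eye filter `E(ρ) = ρ^1.5·exp(−cρ²)` peaking at 4 cycles/degree
  under configurable viewing conditions (a squared-NPS variant is
  available via `nps_exponent = 2`).
* **Statistics** — percent-difference summaries and a paired Wilcoxon
  signed-rank test with Pratt zero handling and exact enumeration for
  small samples.
* **Synthetic phantom generator** — uniform and insert scenes with known
  noise magnitude, known noise texture (`S(f) ∝ f·e^(−f/f0)`), known
  insert contrast and known Gaussian edge blur, so that every stage is
  validated against analytic ground truth. `generate_study()` emulates a
  complete two-version × three-level × four-energy × three-replicate
  phantom study whose noise magnitudes and iodine contrasts follow the
  published measurement tables shipped under `inst/extdata/`.

Stacks are read and written in a simple native format (text header +
16-bit voxel block) and as uncompressed little-endian DICOM series.

## Worked example

The numbered scripts under `analysis/` run the whole study emulation and
write tables under `results/`:

```sh
Rscript analysis/01_simulate_study.R   # generate + measure all 72 stacks
Rscript analysis/02_nps_summary.R      # noise magnitude and texture
Rscript analysis/03_ttf_summary.R      # spatial resolution
Rscript analysis/04_detectability.R    # NPWE d'
Rscript analysis/05_compare_report.R   # paired comparisons + table arithmetic
```

Output of a run:

```
Example finding: measured noise magnitude for (V1, mild, 40 keV) replicates:
  99.7, 99.7, 100.3 HU (generator target 100.2 HU).
Noise-magnitude recovery error across all 24 conditions: -0.84% to 0.06%.
f_av is higher with V2 than V1 at 40-50 keV by 26% on average.
Median TTF50 recovery error for keV >= 50: -0.3% (n = 18 cells).
V1: mean d' over levels and concentrations peaks at 70 keV (40:7.2 50:8.5 60:12.1 70:16.6).
V2: mean d' over levels and concentrations peaks at 60 keV (40:14.9 50:17.2 60:20.3 70:19.2).
d'(V2) > d'(V1) in 27 of 27 cells at 40-60 keV (ratio 1.33-2.32).
Simulated noise drop V2 vs V1 at the standard level: -36.3% (published: -36.5%).
```

Reading: the pipeline recovers the generator's noise targets to within
1%, and the emulated study reproduces the published qualitative findings
— the newer reconstruction version halves the low-energy noise at equal
texture or better, raises the TTF50, and shifts the optimal VMI energy
for low-iodine-detection from 70 keV down to 60 keV.

A minimal interactive session:

```r
library(ctiq)
stack <- generate_uniform_stack(scene_spec(
  512, 0.488, n_slices = 40,
  noise = noise_model(25, "ramp_gauss", f0_mm_inv = 0.15, seed = 1)))
res <- compute_nps(stack, default_nps_rois(stack, 128L))
res
#> <nps_result> noise magnitude 25 HU, f_av 0.291 1/mm (160 ROI instances)
```

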