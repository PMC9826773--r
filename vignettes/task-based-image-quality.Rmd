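---
title: "Task-based CT image quality: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-based CT image quality: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`ctiq` implements a task-based image-quality pipeline for CT slice stacks
in Hounsfield units, of the kind used to characterize reconstruction
algorithms on quality-assurance phantoms: noise power spectrum (NPS) with
noise magnitude and average spatial frequency, task transfer function
(TTF) by the circular-edge method, iodine contrast on virtual
monoenergetic images (VMIs), and the detectability index d' of a
non-prewhitening model observer with eye filter (NPWE) for low-contrast
disk tasks. Because the scanner images behind the study design this
package emulates are not publicly deposited, the package includes a
synthetic phantom generator with fully known ground truth; every analysis
stage is validated against analytic oracles rather than against
irreproducible absolute measurements.

## Noise power spectrum

For square ROIs of $N \times N$ pixels with pixel sizes
$\Delta_x, \Delta_y$ (mm), the 2D NPS is the ensemble average of
detrended periodograms,

$$\mathrm{NPS}_{2D}(f_x,f_y) \;=\; \frac{\Delta_x \Delta_y}{N_x N_y}\,
\frac{1}{n_{\mathrm{ROI}}} \sum_{i=1}^{n_{\mathrm{ROI}}}
\bigl|\mathrm{FFT}_{2D}\{\mathrm{ROI}_i - \mathrm{FIT}_i\}\bigr|^2,$$

where $\mathrm{FIT}_i$ is a least-squares second-order polynomial surface
($1, x, y, x^2, xy, y^2$; coordinates centered and scaled for
conditioning). The ensemble runs over every ROI on every slice — four
128-pixel ROIs on 40 slices gives 160 instances in the reference layout
(`default_nps_rois()`). No window or taper is applied beyond detrending.

Two scalar descriptors are derived:

* **Noise magnitude** — defined here as
  $\sqrt{\iint \mathrm{NPS}\,df_x\,df_y}$, i.e. the standard deviation of
  the detrended noise (Parseval). Task-based IQ reports typically quote
  this quantity in HU without defining it; the convention is recorded in
  the result object.
* **Average spatial frequency** —
  $f_{av} = \int f\,\mathrm{NPS}(f)\,df \,/\, \int \mathrm{NPS}(f)\,df$
  on the radially rebinned 1D profile, by trapezoidal quadrature. Lower
  $f_{av}$ means a blotchier texture.

Radial rebinning choices: the default bin width is one 2D frequency step
$1/(N\Delta)$; each bin reports the mean radial frequency of its samples
(not the nominal center), which removes an upward bias of about 1% in
$f_{av}$ for flat spectra; samples beyond the axis Nyquist are excluded
so that corner frequencies (present only along the diagonals) cannot
distort the profile, and the flat-spectrum check
$f_{av} = f_N/2$ stays exact.

## Task transfer function

The circular-edge method pools every pixel of a circular analysis region
around the insert into a radius-vs-HU cloud (20 slices by default),
bins it radially (default bin width 0.1 pixel — the circular geometry
oversamples the edge), differentiates the edge spread function (ESF) by
central differences into a line spread function (LSF), and normalizes the
modulus of the LSF's Fourier transform to 1 at zero frequency. TTF50 is
the first downward crossing of 0.5, by linear interpolation.

The insert center is estimated as the HU-weighted centroid of the
thresholded insert region (robust 10th/90th-percentile levels), giving
sub-pixel accuracy.

Conditioning choices, all exposed as arguments:

* **ESF smoothing** — a 3-bin moving average before differencing
  (`smooth = TRUE`), recommended for noisy data and disabled in noiseless
  validation.
* **Uniform radial grid** — ESF bins are nominal centers, so the
  finite-difference step is constant; empirical per-bin radii were tried
  and rejected because the irregular step turns bin-level noise into
  large derivative noise.
* **Peak guarding** — the LSF peak (used for windowing and for the edge
  radius) is searched only among bins holding at least half the median
  pixel count; the innermost annuli contain very few pixels and can carry
  arbitrarily large derivative noise.
* **Tukey window** — the LSF is tapered to zero outside roughly three
  times its full width at half maximum around the peak (flat over the
  main lobe, cosine rolloff). This suppresses the tail-noise floor that
  otherwise biases the TTF upward at low contrast-to-noise ratio, and is
  inert for noiseless data.
* **Baseline correction** — the mean of the LSF tails is subtracted
  before the transform.
* **Insert contrast** — mean ESF well inside the edge minus well outside,
  used as the contrast input downstream.

With a Gaussian edge blur of standard deviation $\sigma_b$ the ground
truth is $\mathrm{TTF}(f) = \exp(-2\pi^2\sigma_b^2 f^2)$ and
$\mathrm{TTF}_{50} = \sqrt{\ln 2 / (2\pi^2\sigma_b^2)}$; the test suite
checks recovery to 3% noiseless and 10% at contrast-to-noise ratio 6.
At much lower contrast-to-noise ratio (the 40 keV cells of the study
emulation reach noise 100 HU against a 220 HU insert) individual TTF50
estimates become unstable and may fail to cross 0.5 at all; such cells
report `NA` for TTF50 while the TTF curve still feeds the detectability
stage, where its influence is small because the 10-mm disk task
concentrates at frequencies where the TTF is near 1.

## NPWE detectability index

For a disk task of radius $R$ and contrast $C$, the task function is
$W(\rho) = C\,\pi R^2 \left|2J_1(2\pi R\rho)/(2\pi R\rho)\right|$ and

$$d'^2 \;=\;
\frac{\left[\iint |W|^2\,\mathrm{TTF}^2\,E^2\,du\,dv\right]^2}
     {\iint |W|^2\,\mathrm{TTF}^2\,\mathrm{NPS}^{p}\,E^4\,du\,dv},$$

evaluated by Riemann sums on a $256^2$ Cartesian grid spanning the
reconstruction Nyquist (doubling the grid changes d' by under 0.03%).
Radial TTF and NPS measurements are linearly interpolated onto the grid;
beyond their measured range the TTF continues as its last value and the
NPS as zero.

Three design questions had no single established answer and are resolved
as explicit, configurable defaults:

* **Eye filter** — model-observer practice names the eye filter but
  rarely prints its form. The package uses
  $E(\rho) = \rho^{1.5}\exp(-c\rho^2)$ in cycles/degree, normalized to a
  unit peak at 4 cycles/degree ($c = 0.75/16$); exponent and peak are
  arguments.
* **NPS exponent $p$** — the standard NPWE denominator uses the NPS once
  ($p = 1$, the default); a squared-NPS variant appears in some printed
  formulations and is available as `nps_exponent = 2`. Both are tested;
  the homogeneity law $d' \propto \mathrm{NPS}^{-1/2}$ refers to $p = 1$.
* **Display conversion** — viewing conditions (zoom 1.5, 500 mm distance,
  300-mm field of view, 0.05-mm display pixel) enter through the
  magnification $M = \mathrm{zoom} \times \Delta_{\mathrm{disp}} /
  \Delta_{\mathrm{img}}$ with $\Delta_{\mathrm{img}}$ implied by the
  displayed field of view over the matrix size; angular frequency is
  $f/M \times d \times \pi/180$. The 0.05-mm figure is read as the
  display pixel pitch; all display parameters are arguments of
  `display_model()`.

## Synthetic phantom generator

The generator provides ImageStacks whose statistics are known exactly:

* **Noise** — white Gaussian fields shaped in the frequency domain by
  $\sqrt{S(f)}$, normalized over the discrete grid so the field variance
  equals $\sigma^2$ in expectation and the DC term is zeroed (exact zero
  mean). The CT-like texture family is $S(f) \propto f\,e^{-f/f_0}$
  (rises then falls); $f_0$ tunes $f_{av}$.
* **Inserts** — disks of known contrast convolved with an isotropic
  Gaussian PSF. The blurred radial profile is computed by stable
  quadrature of the exact 2D convolution (a Marcum-Q-type integral with
  exponentially scaled Bessel $I_0$), so the ground-truth TTF is exactly
  Gaussian — the 1D error-function approximation is avoided.
* **Slices** — independent noise realizations over a fixed noiseless
  scene. Real CT has inter-slice noise correlation; since the analysis
  treats slices as ensemble members, independence is the cleanest null
  structure, and it is a documented divergence from real data.

`generate_study()` assembles the full study design (2 versions x 3
reconstruction levels x 4 VMI energies x 3 replicates) with:

* noise magnitudes set to the published noise table and iodine contrasts
  to the published contrast table (shipped as transcribed CSV fixtures);
* texture parameters $f_0$ per (version, level, keV) chosen once to
  reproduce the published texture trends qualitatively ($f_{av}$ falls
  with increasing reconstruction level; V2 sits 25-40% above V1 at 40-50
  keV; V2 falls by about a quarter from 40 to 60 keV; both rise slightly
  at 70 keV) — the study prints no raw texture values to fit;
* edge blur $\sigma_b$ per (version, level, keV) derived from the
  published TTF50 values through the Gaussian closed form, interpolating
  across keV where only endpoints are printed;
* an acrylic-like TTF insert whose contrast rises toward low keV
  (220/170/140/120 HU at 40/50/60/70 keV) as acrylic does on VMIs — the
  study does not print these values, and a constant low contrast would
  make the 40 keV TTF unmeasurable at 100 HU noise;
* the same noise model for the multi-energy contrast scenes as for the
  uniform module at the matching condition (the study reports no separate
  noise for that phantom);
* deterministic seeds: replicate $r$ of condition $i$ derives its seed
  from a single base seed, $i$ and $r$.

What the generator does **not** emulate: projection-domain physics, beam
hardening, dual-energy anti-correlated noise, inter-slice correlation,
and any nonlinearity of the reconstruction algorithms themselves.
Passing tests therefore demonstrate that the estimators recover known
image-domain statistics under realistic magnitudes — not that they would
reproduce a particular scanner's absolute numbers.

## Statistics

Percent differences are $100\,(b-a)/a$ with the first-named condition as
reference; replicate summaries are mean and sample SD. The paired
comparison test is the two-sided Wilcoxon signed-rank test with zero
differences handled by the Pratt method (zeros are ranked, then dropped).
For up to 15 nonzero differences the null distribution is enumerated
exactly conditional on the observed absolute differences (so ties are
exact as well); beyond that a normal approximation with tie, zero and
continuity corrections is used. The base-R `wilcox.test` cannot serve as
the implementation here — it has no Pratt handling and refuses exact
p-values under ties — but it is used as an independent cross-check on
clean inputs, and a brute-force sign-enumeration oracle checks all small
cases. No multiple-testing correction is applied, matching the reporting
convention the package reproduces.

A note on one reported invariant of the percent difference: under
exchange of arguments the identity is
$\mathrm{pd}(a,b) = -\mathrm{pd}(b,a)\cdot b/a$ (both sides equal
$100\,(b-a)/a$).

## Problem sizes and numerical tolerances

The validation suite and the acceptance script use scaled problem sizes
chosen to exercise every estimator at realistic statistics: uniform
stacks of 256 pixels x 10 slices with four 64-pixel ROIs for the study
emulation (full 512 x 40-slice geometry with 128-pixel ROIs for the
calibration checks), 128-pixel insert stacks with 20 slices for the TTF,
and three replicates throughout. Noise-magnitude recovery is within 3%,
texture ($f_{av}$) within 5%, noiseless TTF50 within 3% (10% at
contrast-to-noise ratio 6), and the trivial-observer d' closed form
within 1% on the default grid. File round-trips store HU as 16-bit
integers with slope/intercept, exact to 0.5 HU over the CT range.

## Known limitations

* DICOM support covers uncompressed little-endian single-frame CT series
  (read and write); compressed transfer syntaxes are rejected.
* The TTF estimator assumes a high-contrast circular insert; at
  contrast-to-noise ratios well below 2 its TTF50 becomes unreliable and
  is reported as `NA`.
* The NPWE model here is 2D and single-slice, with no internal-noise
  term; detectability values are comparative, not absolute predictions
  of human performance.
* The generator's texture and acrylic-contrast defaults are qualitative
  emulation choices, adequate for ordering-level conclusions but not for
  reproducing absolute printed TTF50 or d' magnitudes.
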