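# biofluo

An in-silico model of an integrated preclinical imaging platform that
records planar bioluminescence and fluorescence images and SPECT scans of
the same subject in one session. A digital phantom — a cylinder of
tissue-simulating gel with a thin capillary (0.9 mm inner diameter)
inserted at an oblique angle and uniformly filled with a fluorescent dye
plus a gamma emitter — stands in for the physical instrument. The package
then reproduces the platform's processing and characterization chain:

* **Optical processing** — flat-field illumination correction (Gaussian
  blur of the calibration image, FWHM 7.30 mm, normalized to max 1,
  pixel-wise division), 4 × 4 median filtering of gamma-induced hot
  pixels, the half-ADC exposure rule, and counts/s normalization.
* **SPECT chain** — list-mode energy windowing (20% photopeak window,
  e.g. 126–154 keV around the 140 keV Tc-99m peak), triple-energy-window
  (TEW) scatter correction with flanking windows (124–136 and
  166–184 keV), OSEM reconstruction (16 subsets, 6 iterations) on a
  parallel-beam toy geometry, 3-D Gaussian post-filtering (FWHM 0.47 or
  1.18 mm), and vertical/lateral sum projections.
* **Fusion** — thresholded color overlay of any emission image on the
  grayscale photo, with mask-moments similarity registration replacing
  manual contour matching.
* **Characterization** — ~1 mm wide line profiles along and orthogonal to
  the capillary, depth mapping via the inclination angle
  (`depth = entry + Δx · tan θ`), signal-versus-depth and FWHM-versus-depth
  curves, peak-to-background ratios, detectability depth
  (mean + 3 SD criterion), and recovery of the effective optical
  attenuation coefficient.

## The model in brief

Fluorescence from a source element at depth `z` reaches the camera
attenuated by a single effective exponential and blurred by a
depth-growing Gaussian:

    I(x, y) ∝ L(x, y) · Σ_elements  A · exp(−(μ_ex + μ_em) z) · G_{σ(z)},
    σ(z) = σ₀ + k z,       FWHM = 2√(2 ln 2) · σ

with `L` the illumination field and an excitation-leakage +
autofluorescence background expressed as a fraction of the unattenuated
peak. Bioluminescence uses the same model with no illumination, no
leakage, and `μ_em` only. Gamma events are unattenuated (gamma
self-attenuation in the gel is negligible and no attenuation correction
is applied), so the reconstructed SPECT profile along the capillary is
flat while the fluorescence signal decays — the core contrast the
characterization quantifies.

## Worked example

```r
library(biofluo)
res <- run_pipeline(out_dir = "run1")   # default seeded configuration
str(res$summary)
```

prints (seed 1, default desk-scale configuration):

```
$ mu_fluorescence_per_mm     : num 0.0802
$ mu_fluorescence_ci         : num [1:2] 0.0773 0.0831
$ mu_true_per_mm             : num 0.08
$ mu_spect_per_mm            : num 0.00848
$ mu_spect_ci                : num [1:2] 0.000495 0.016464
$ detectability_depth_mm     : chr "beyond range"
$ exposure_check_fluorescence: chr "ok"
$ n_events                   : int 24313
$ sinogram_discarded         : int 46
```

Reading: the fluorescence chain recovers the generator's effective
attenuation coefficient (0.0802 vs 0.08 /mm true; the CI covers truth),
while the SPECT curve's fitted coefficient is an order of magnitude
smaller — flat within reconstruction noise (across seeded replicates its
ensemble CI covers 0; a single run can drift by ±0.01). The fluorescence
exposure satisfies the half-ADC rule, and the capillary stays detectable
over the whole simulated depth range at this photon budget. The run
directory holds every intermediate (TIFF/NIfTI/CSV/PNG), `run.log`, and
`provenance.json` for bit-identical reruns.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "biofluo", package = "biofluo"))')
Rscript $CLI run --seed 1 --out run1
Rscript $CLI reconstruct --events run1/events.csv --subsets 16 \
        --iterations 6 --postfilter-fwhm-mm 0.47 --out vol.nii
Rscript $CLI project --in vol.nii --axis vertical --out sum.tif
Rscript $CLI overlay --base run1/photo.tif --signal sum.tif \
        --threshold 0.3 --colormap hot --transform auto --out overlay.png
```

(Option values that begin with `-`, such as line coordinates, must use
the `--option=value` form.)

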