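# memgp — membrane order imaging analysis

Quantitative image analysis for **polarity-sensitive membrane dyes**
(Laurdan, Di-4-ANEPPDHQ, Di-4-AN(F)EPPTEA, NR12S and relatives) in confocal
and STED microscopy. These probes red-shift their emission in loosely packed
(disordered) lipid environments, so the spatial pattern of their emission
color reports membrane lipid order — in giant plasma-membrane vesicles
(GPMVs), live-cell plasma membranes, endocytic vesicles and single virus
particles. `memgp` implements the four analysis stages such experiments
need, plus a synthetic phantom generator that provides complete ground truth
for validating every stage.

## What it computes

**Generalized polarization (GP) maps.** From an ordered (blue, e.g.
520–570 nm) channel *I₁* and a disordered (red, e.g. 620–700 nm) channel
*I₂*, the pixel-wise index

&nbsp;&nbsp;&nbsp;&nbsp;GP = (I₁ − I₂) / (I₁ + I₂) ∈ [−1, +1],

with +1 maximally ordered and −1 maximally disordered. Background pixels
(summed intensity below a configurable fraction of the image maximum) are
masked to `NaN`. ROI means ± SD, interdomain differences, and a red(+1)-to-
blue(−1) rendering follow (`compute_gp_map`, `roi_gp_stats`,
`interdomain_difference`, `render_gp_colormap`).

**Membrane-width FWHM profiling.** Since the bilayer (≈8 nm) is far below
optical resolution, the apparent width of a membrane image measures the
effective point spread function. A traced contour is resampled at regular
arc-length intervals (default 3 px); at each anchor a perpendicular
40-px line profile is extracted by bilinear interpolation and fit with a
Gaussian; the width follows as FWHM = 2√(2 ln 2)·σ, and confocal/STED mean
ratios quantify the resolution gain (`resample_contour`, `extract_profile`,
`fit_gaussian_profile`, `summarize_fwhm`, `resolution_ratio`).

**λ-stack spectral analysis.** ROI emission spectra from stacks of
consecutive 9-nm spectral windows, peak positions with parabolic sub-window
refinement, the ordered/disordered peak shift, per-window intensity ratios,
and recombination of window ranges into a two-channel image
(`extract_spectrum`, `peak_shift`, `channel_intensity_ratio`,
`recombine_bands`).

**Photostability.** Per-frame ROI means of a sequential acquisition
normalized to the first frame, fractional loss after *N* frames, and a
single-exponential per-frame survival fit (`bleach_curve`,
`fractional_loss`, `fit_decay`).

**Phantom generator.** `phantom_spec`/`render_phantom` rasterize membrane
rings (with angular phase arcs) and sub-resolution discs on a supersampled
grid, convolve with a Gaussian PSF (presets: confocal 240 nm, STED 80 nm
FWHM), split photons across detection bands or λ windows per phase, and add
Poisson noise — returning the image stack together with ground truth and
measurement ROIs. Named presets (`phantom_preset`) cover the standard
scenarios; `render_phantom_replicates` draws independent noise realizations
of one specimen.

## Worked example

A phase-separated vesicle with a 500-nm nanodomain of lower lipid order,
imaged with the STED preset and analyzed with the GP pipeline:

```r
library(memgp)
spec <- phantom_preset("fig5-nanodomain", seed = 7)   # STED PSF (80 nm FWHM)
ph   <- render_phantom(spec)
map  <- compute_gp_map(ph$stack)          # (I1 - I2)/(I1 + I2), 10% mask
map
#> gp_map: 280 x 280 px, 4507 valid pixels (threshold 53.8)
#>   GP range: -0.452 .. 0.440
stats <- roi_gp_stats(map, ph$rois)
stats[stats$label %in% c("domain", "surround"), ]
#>     label     mean_gp      sd_gp n_pixels n_masked
#>    domain -0.19668231 0.08815253      103       69
#>  surround  0.08456668 0.07455257      109       63
```

The 150-nm-radius domain ROI recovers the generative truth (GP −0.19 for
the domain, 0.08 for the surrounding membrane): the domain is ~0.28 GP units
more disordered than its surround. Under the confocal preset
(`psf_fwhm_nm = psf_presets()[["confocal"]]`) the same ROI reads a smaller
GP magnitude, because the 240-nm PSF mixes surround photons into the domain
— the reason nanodomain GP imaging needs super-resolution.

Resolution estimation on the uniform-vesicle phantom:

```r
sted <- phantom_preset("fig3-gpmv", psf_fwhm_nm = psf_presets()[["sted"]],
                       noise = "poisson")
reps <- render_phantom_replicates(sted, seeds = 1:3)
fits <- unlist(lapply(reps$stacks, function(s)
  profile_image_fwhm(s$pages[[1]], reps$truth$contour)), recursive = FALSE)
summarize_fwhm(fits, pixel_size_nm = 20)
#> fwhm_summary: 83.6 +/- 1.7 nm (n = 1572 used, 0 rejected)
```

The measured 83.6 nm slightly exceeds the 80-nm PSF because pixel binning
and bilinear sampling add a small, known amount of width (see the methods
vignette).

## Command line

`inst/scripts/memgp` is a thin dispatcher over the same functions:

```sh
memgp simulate --preset fig5-nanodomain --psf sted --seed 7 --out run/
memgp gpmap    --image run/phantom.tif --roi run/phantom_rois.json --out run/
memgp fwhm     --image img.tif --roi roi.json --pixel-size-nm 20 --spacing 3 --length 40
memgp spectra  --stack stack.tif --roi roi.json --bands 513:693 --recombine 500:530,570:691
memgp bleach   --stack series.tif --roi roi.json --frames 20
```

Each subcommand writes CSV results plus a JSON run-parameters record;
identical inputs and seed reproduce outputs bit-identically. Images are
multi-page grayscale TIFF (lossless 32-bit float, `NaN`-safe); ROIs are a
documented JSON schema (`load_rois`/`save_rois`).

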