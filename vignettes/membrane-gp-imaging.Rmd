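---
title: "Methods: GP mapping, FWHM profiling and phantom validation in memgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GP mapping, FWHM profiling and phantom validation in memgp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memgp)
```

`memgp` quantifies membrane lipid order and imaging resolution from
confocal/STED images of polarity-sensitive dyes. This vignette documents the
underlying models, the numerical choices, and exactly what the bundled
phantom generator does and does not emulate — so that a reader can judge
what a passing validation suite implies about real data.

## Conventions

Pixel coordinates are 0-based pixel centers, `(x, y)` = (column, row), `y`
increasing downwards; an R matrix element `M[r, c]` is the pixel
`(c - 1, r - 1)`. Angles on a vesicle ring are degrees from the +x axis
towards +y. Intensities are treated as linear photon-proportional counts:
no detector calibration, gamma, or offset model is applied anywhere.

Images travel as multi-page grayscale TIFF. The package writes uncompressed
32-bit IEEE-float pages through its own minimal baseline-TIFF encoder, which
makes every round-trip bit-lossless including `NaN` (used for masked
pixels); 16-bit unsigned integer output is available for plain count data.
ROIs are stored as a small documented JSON schema (polylines and circles
with purpose tags) rather than a binary format, for diff-ability and
testability.

## Generalized polarization

For an ordered-channel image $I_1$ and a disordered-channel image $I_2$
(typically 520–570 nm and 620–700 nm detection bands), the generalized
polarization is computed per pixel:

$$\mathrm{GP} = \frac{I_1 - I_2}{I_1 + I_2} \in [-1, +1].$$

GP is a ratio of noisy counts, so it is meaningless where the denominator is
small. `compute_gp_map(mask_fraction = 0.1)` masks every pixel whose summed
intensity falls below 10% of the maximal summed intensity in the image. The
threshold is the one genuinely free parameter of the GP stage; 10% keeps the
membrane and drops lumen and background in all bundled scenarios while
keeping the denominator well-conditioned. Masked pixels are `NaN`, valid GP
values are never rescaled, and an all-zero channel pair yields a fully
masked map with a warning rather than an error.

ROI statistics (`roi_gp_stats`) use the arithmetic mean ± SD of per-pixel GP
values over the valid pixels inside the ROI; pixels inside the ROI but
masked are excluded and reported in a separate count. The alternative
statistic — GP of the summed channel intensities, which weights pixels by
brightness — is available as `roi_gp_stats_weighted`; per-pixel averaging is
the default because reported "average ± SD" domain values imply it. An
optional per-channel gain pair (`gains =`) supports G-factor-style channel
calibration, but the default applies none: two-band GP is conventionally
reported uncorrected, and any fixed gain cancels in interdomain
*differences*, which are the transferable readout
(`interdomain_difference`, SD propagated as the root sum of squares).

One systematic effect is worth naming: in STED mode the depletion beam
suppresses red-shifted emission slightly more than blue-shifted emission,
biasing absolute GP upward. The analysis module never corrects for this —
absolute GP is instrument-specific by nature — but the phantom can emulate
it through per-channel transmission factors if a user wants to study the
effect.

`render_gp_colormap` maps GP linearly onto a red(+1)–blue(−1) lookup: RGB
interpolates from pure blue through (0.5, 0, 0.5) at GP 0 to pure red, with
masked pixels black and optional brightness modulation by total intensity.

## Membrane-width (FWHM) profiling

The lipid bilayer is ≈8 nm thick — one to two orders of magnitude below
optical resolution — so the apparent width of an imaged membrane is, to very
good approximation, the effective PSF width. The profiler reimplements the
bulk-measurement idiom familiar from ImageJ macros:

1. **Contour resampling** (`resample_contour`): anchors at arc-length
   multiples of `spacing_px` (default 3 px) along the traced polyline,
   starting at vertex 0, final partial interval dropped. Tangents are
   central differences across neighboring anchors (wrapped for closed
   contours, one-sided at open ends); normals are tangents rotated +90°.
   The tangent scheme is this package's choice — any local estimator works
   at the 3-px spacing used.
2. **Profile extraction** (`extract_profile`): intensities sampled by
   bilinear interpolation at unit offsets along the normal over
   `[-L/2, +L/2]`, default `L = 40` px. A profile whose endpoints leave the
   image is *rejected*, not an error, so border anchors simply drop out.
3. **Gaussian fitting** (`fit_gaussian_profile`): least squares of
   $b + A\exp(-(x-c)^2/2\sigma^2)$ via Levenberg–Marquardt
   (`minpack.lm::nls.lm`) with an analytic Jacobian. Initialization is
   data-driven: offset = min, amplitude = max − min, center = argmax
   position, sigma = second moment of the background-subtracted profile
   about the argmax. The low-level optimizer is used deliberately: the
   formula-based interface refuses exact (zero-residual) data, which the
   validation suite relies on.
4. **Width**: $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$, converted to nm by
   the pixel size (default 20 nm/px, the usual STED-optimized sampling).

**Fit acceptance rules.** A fit is discarded (excluded from summaries) when
the optimizer fails, $\sigma \notin (0.5, L/4)$ px, $|c| > L/4$, or
$A < 2\hat\sigma_\text{noise}$ where $\hat\sigma_\text{noise}$ is the
residual SD of the fit. These bounds are this package's own additions — how
bad fits were excluded is never stated in macro-based workflows — and they
are all configurable. They reject flat (background) profiles, profiles
dominated by a second membrane in the window (either the off-center lock or
the inflated-σ misfit trips a rule), and border artifacts. A constructed
bimodal fixture pins this behavior in the test suite.

**Aggregation** (`summarize_fwhm`): mean ± SD over converged fits, pooled
over all profiles; when image identifiers are supplied, per-image means and
their average are reported as well, since "average over ≥10 images" and
"pool all profiles" differ in principle. Both are exposed; for the phantom
scenarios they agree to well within the SD. `resolution_ratio` divides
confocal by STED means with first-order error propagation.

**Known bias.** Pixel-area integration (box binning) and bilinear sampling
each convolve the profile with a kernel of variance $p^2/12$ and up to
$p^2/6$ ($p$ = pixel size), so the measured width slightly exceeds the true
PSF FWHM: at $p = 20$ nm this inflates an 80-nm PSF by ≈4% and a 240-nm PSF
by ≈0.5%. This is a property of the measurement (shared by any
pixel-sampling implementation), not of the fit — the suite's recovery test
therefore runs at 10 nm/px, where the inflation is within 2%, and the
closed-form oracle test samples exactly on pixel centers to isolate the fit
itself (<0.1%). The confocal/STED *ratio* is much less affected since both
modalities share the pixel grid; the phantom study's expected ratio for
240 nm / 80 nm presets is ≈2.9 rather than exactly 3.0, comfortably inside
the ±10% acceptance band.

## λ-stack spectral analysis

A λ stack samples the emission spectrum in consecutive 9-nm windows
(presets span 513 nm upward in twenty windows). Throughout, a window is
represented by its center wavelength. `extract_spectrum` is the per-window
ROI mean, optionally normalized to unit maximum (idempotently).

Peak positions (`peak_wavelength`) default to parabolic refinement — the
vertex of the parabola through the maximal window and its neighbors — which
recovers sub-window peak positions from 9-nm-binned Gaussians to well under
1 nm; `argmax_bin` is retained for strict binned readout, and the parabolic
method falls back to it at the axis edge or when the three points are not
locally concave. `peak_shift` is disordered-peak minus ordered-peak
(positive = red shift). `channel_intensity_ratio` flags and excludes
windows with a zero disordered-phase mean instead of dividing by zero.
`recombine_bands` assigns windows to output channels by center position,
with straddling windows included by that same rule, so that disjoint bands
covering the axis partition the total intensity exactly.

Background subtraction before normalization is available as an option but
off by default; spectra of bright membrane ROIs in the bundled scenarios
have no background pedestal. No multi-component unmixing or solvatochromic
lineshape fitting is attempted: separating a second emitter (e.g.
cytoplasmic GFP) is done by band choice alone, which the recombination
operation reproduces.

## Photostability

`bleach_curve` applies one fixed ROI to every frame (no drift correction —
the series emulated are immediate sequential scans of a static field),
normalizes the per-frame means to frame 0, and `fractional_loss(curve, n)`
returns $1 - \text{relative intensity at frame } n-1$ (0-based), so a
20-frame series evaluates the survival after 19 bleaching steps. A
brightening series returns its negative loss as-is with a warning rather
than clamping. `fit_decay` summarizes the curve by a single per-frame
survival $s \in (0, 1.1]$ fit by least squares on $s^k$ (1-D bounded
optimization; the upper bound slightly above 1 accommodates noise around a
non-bleaching series).

## The phantom generator

`phantom_spec`/`render_phantom` produce images with exactly the statistical
structure the four analyses assume, plus full ground truth:

* **Geometry.** The equatorial section of a vesicle is a ring of radius
  $r$ with a rectangular (top-hat) radial cross-section of width 8 nm. At
  ≈8 nm the cross-sectional shape is immaterial after convolution with any
  ≥70-nm PSF, but it must be stated: top-hat it is. Angular arcs partition
  the ring into phases (they must tile the full circle); filled discs model
  sub-resolution objects (endosomes, virions). Arc brightness is photons
  per nm of contour length; disc brightness is photons per nm² (a length
  density has no meaning for a filled disc).
* **Rendering.** Structures are rasterized on a 4× supersampled grid with
  radial anti-aliasing, convolved with an isotropic 2-D Gaussian PSF
  (specified by FWHM; FFT with zero padding), and box-binned back to the
  target 20-nm pixels, making pixel values accurate line integrals of
  membrane brightness — photon count is conserved to quadrature tolerance
  (verified at 0.5%). No depletion-beam physics is simulated: STED vs
  confocal is purely a PSF-width contrast (presets 80 vs 240 nm).
* **Spectral split.** Each phase paints photons either by an explicit
  Gaussian emission spectrum, integrated over the detection bands or λ
  windows (`band_fractions`, exact via the normal CDF, with a delta-line
  limit at zero width), or directly by a channel-1 photon fraction $f$,
  giving ground-truth $\mathrm{GP} = 2f - 1$.
* **Noise and bleaching.** Poisson noise, independent per pixel and page,
  after all expected-value computation; bleaching scales the expected
  image by $s^k$ before the noise draw. Identical spec + seed reproduces
  output bit-identically; `render_phantom_replicates` reuses the expensive
  expected field across independent noise draws.

**Preset calibration.** The named presets are the smallest generative
setups that exercise each pipeline at realistic operating points: vesicle
radii 2–5 µm, membrane brightness 100 photons/nm (peak pixel counts of a
few hundred, typical of a good STED frame), a 500-nm nanodomain with
channel fractions 0.405/0.540 (GP −0.19/0.08), a 150-nm disc at 0.555 near
a membrane at 0.660 (GP 0.11/0.32), emission peaks 570/610 nm with 25-nm
spectral SD, and per-frame survival 0.9875 over 20 frames (≈21% total
loss). Measurement ROIs are 150-nm-radius circles at arc/object centers
(300 nm for the spectral and bleaching presets, where larger membrane
patches are the natural readout).

**What the phantom does *not* emulate** — and hence what passing tests do
not establish about real data: aberration-induced PSF asymmetry and depth
dependence, wavelength-dependent PSF width across a λ stack, depletion-beam
spectral bias on GP (available only as an explicit option), detector read
noise and afterpulsing, membrane undulations and out-of-plane geometry,
sample drift during series, and autofluorescent or scattering backgrounds.
The validation establishes that the *estimators* are correct on data
matching their model assumptions, with Poisson statistics at realistic
counts — not that those assumptions hold on any particular microscope.

## Problem sizes and numerics

The validation suite runs the full resolution study on ten 600×600-px noise
replicates per modality (≈500 profiles each), and the GP/spectral/bleaching
recoveries on 280×280-px phantoms — sizes chosen so the complete suite and
the reproduction script each finish in well under a minute or two on a
single core while leaving every estimate's Monte-Carlo error far below the
acceptance tolerances. Degenerate inputs are handled explicitly rather than
by crashing: flat profiles and all-zero spectra/channels report
non-convergence, a warning-carrying masked map, or a named error; ROIs that
select no valid pixels name the offending ROI; malformed geometry
(overlapping bands or arcs, duplicate ROI labels, mismatched page shapes)
is rejected at construction time with a message naming the violation.
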