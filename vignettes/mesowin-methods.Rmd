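---
title: "Models and methods behind mesowin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mesowin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mesowin` implements the image-analysis chain used to evaluate transparent
cranial windows in awake mice: speckle-based flow mapping, an Otsu
vessel-area transparency statistic, interhemispheric homotopic functional
connectivity around cortical spreading depolarization (CSD), and microglia
morphology via Sholl analysis. This vignette documents the models, the
parameters that matter, the synthetic generators used for validation, and
the design decisions taken where the underlying procedure is ambiguous.

## Conventions

All pixel coordinates in this package are 1-based `(row, col)` pairs with
the row index increasing downward, matching R's matrix indexing; landmark
JSON files use the same convention. Image stacks are 3-D arrays indexed
`(frame, row, col)`. Raw data are 8- or 16-bit grayscale TIFF stacks with
a JSON sidecar carrying acquisition metadata (pixel size in um, frame
rate in Hz, exposure in ms); derived floating-point maps (contrast, flow
index, z-maps) are written as 32-bit float TIFF pages min-max scaled to
[0, 1] with the affine map recorded in the sidecar, because flow-index
and z values exceed the integer display range.

## Laser speckle contrast and the flow index

The speckle contrast at a pixel is `K = sigma / mu`, the sample standard
deviation over mean of intensities in a sliding `7x7` window (sample sd
with the `n - 1` denominator, fixed so tests are exact). Moving red blood
cells decorrelate the speckle field within the camera exposure `T`
(5 ms), blurring the pattern and lowering `K`; the flow index is
`ICT = 1 / K^2`, larger for faster flow. The window computation uses the
valid region only: the border of half-window width is flagged invalid
rather than padded, because padding fabricates contrast at edges. Pixels
with a zero window mean are flagged, not raised as errors. Internally the
windowed moments are computed from globally centered intensities via
integral images, which keeps the cancellation error of the variance below
1e-10 against a direct double-loop evaluation.

Acquisition bookkeeping follows the recording design: 15 raw frames per
image set and 9 flow-index images averaged per output stack
(`average_ict_stack`, valid where all inputs are valid).

**Ordering ambiguity.** A set of raw frames can be (a) averaged first,
with `K` computed on the average (`mode = "literal"`, the default,
following the stated processing order) or (b) converted to per-frame `K`
images that are then averaged (`mode = "per_frame"`, the more common
field practice). When frames decorrelate between exposures the two differ
substantially — temporal averaging in (a) suppresses contrast further —
so both are exposed and the choice is explicit, never silent.

**rBF traces.** `relative_flow_trace` divides the ROI-mean flow index by
its mean over a baseline frame range; the trace is dimensionless,
averages to 1 over the baseline, and is invariant to any positive
rescaling of intensities.

**Occlusion.** Drying artifacts and bubbles appear near-black on averaged
LSCI images. The manual procedure (delineated polygons) is reproduced by
`method = "polygons"`; `method = "auto"` is a reproducible surrogate that
thresholds at `min + dark_frac * (max - min)` of the within-window
intensity range (default `dark_frac = 0.02`) and keeps connected dark
components of at least 50 px to suppress single-pixel noise. A fraction
of the intensity *range* (not an intensity quantile) is used because the
occluded area itself can be an arbitrary fraction of the window; a
contrast-free window reports 0%.

## The transparency statistic

IOSI reflectance at 530 nm is strongly absorbed by hemoglobin, so
resolved vessels are dark. Within a manually drawn brain mask (artifact
and inflammation regions subtracted via exclusion polygons before
thresholding), the image is auto-thresholded by Otsu's criterion and the
percentage of masked pixels in the **dark** class is reported as the
vasculature percentage — a clearer window resolves more vasculature. The
dark-class polarity is a package decision (the absorption physics makes
it the only sensible reading); it is stated here because the underlying
procedure does not name the class.

Otsu implementation: candidate thresholds are the interior edges of a
256-bin grid spanning the masked min-max (deterministic across 8- and
16-bit inputs); the between-class variance of the exact masked values is
maximized, ties taking the lowest threshold. Tests verify exact equality
with an exhaustive-search oracle, invariance to pixels outside the mask,
and stability of the vessel percentage under affine intensity rescaling
(within one histogram-bin quantum). A constant masked region raises a
degenerate-input error.

## Homotopic connectivity

The pipeline order is fixed and not configurable:

1. **Downsample** by non-overlapping block means (4x4 for 512 -> 128);
   preserves the per-frame spatial mean exactly.
2. **Detrend**: per-pixel least-squares line subtracted. Linear order is
   a package decision; drifts in these recordings are dominated by slow
   monotone photobleaching/hemodynamic baseline shifts.
3. **Bandpass** 0.035-0.08 Hz: fourth-order Butterworth design applied
   forward-backward (`signal::filtfilt`), i.e. zero phase, so
   band-interior components are not shifted in time. Filter family and
   order are package decisions fixed for determinism. The per-pixel
   temporal mean is subtracted before filtering; the mean is deep in the
   stop band, and removing it first avoids leaking start-up transients.
4. **Global signal regression (GSR)**: each pixel's series is regressed
   on an intercept and the mask-mean time course; residuals are returned
   and are orthogonal to the regressor to numerical precision.

Homotopic pairing mirrors every pixel across the line through bregma and
lambda — the anatomical midline — pairing left with right. The geometry
is deliberately the midline reflection itself: a reflection across a line
*orthogonal* to the midline would pair anterior with posterior tissue,
which is not a homotopic comparison. Mirror positions are rounded to the
nearest pixel (no interpolation, to avoid resampling time series); pixels
on the midline, mirrors falling outside the image or mask, and
zero-variance pixels are dropped from the pairing. Pearson `r` is
computed on mean-centered series, clipped to `|r| <= 1 - 1e-7`, Fisher
transformed (`z = atanh r`), and averaged over paired pixels into the
connectivity index.

**CSD block analysis.** A post-induction recording at 3 fps discards its
first 500 frames (~2.8 min, while the depolarization wave traverses the
hemisphere) and analyzes the remainder as three 10-min blocks (1800
frames each), each run through the full chain alongside a baseline
recording. A 32.7-min recording yields 5886 frames; after the discard,
5386 remain — the third block therefore uses the final available frames
and is flagged `short` in the output rather than erroring, matching the
approximate arithmetic of the block design without inventing data.

## Synthetic generators

The generators produce inputs with exactly the statistical structure each
stage assumes, plus ground-truth JSON; all are seed-deterministic.

**Dynamic speckle.** A complex circular Gaussian field, spatially
band-limited by a circular frequency-domain aperture and evolved in time
as a per-substep AR(1) with coefficient `exp(-dt / tau_c)` — a
Lorentzian-type decorrelation. The camera exposure integrates
`n_substeps` intensity sub-frames (default 16; 64 when `tau_c << T` needs
resolving). Partial coherence `beta` shrinks intensity fluctuations about
the mean so `K^2` scales by `beta`. Intensities are digitized with the
mean at 1/8 of full scale (saturation probability ~e^-8). The *expected*
contrast is taken from a brute-force many-realization simulation of the
same temporal model (`expected_speckle_contrast`), never from a
closed-form visibility formula, to keep model and oracle aligned by
construction. The grain-size convention is `cutoff = 1/grain_px`
cycles/px, i.e. `grain_px = 2` is Nyquist-sampled speckle — the sampling
regime speckle instrumentation aims for and the package default. Note
that windowed `K` on spatially correlated speckle sits slightly below the
global (whole-image) contrast because neighboring window samples are
correlated; at `grain_px = 2` the effect is within the tolerances used.

**Bilateral hemodynamics.** For each mirror pair,
`left = sqrt(rho) s + sqrt(1 - rho) e_L` and
`right = sqrt(rho) s + sqrt(1 - rho) e_R`, with `s, e` independent
unit-variance Gaussian processes synthesized in the 0.035-0.08 Hz band,
on a baseline of 128 counts with a 10-count signal amplitude. Nuisance
terms: linear drift (default 0.01 counts/frame), a common global
component (default 5 counts) and white noise (default 3 counts) — chosen
as a realistic mix of slow baseline shift, brain-wide hemodynamics and
camera noise at 8-bit scale. Pair assignment uses the same mirror
machinery as the analysis, so symmetry is exact by construction. Because
the signals are band-limited, n frames carry only about `2 B T` effective
samples (~54 for 10 min at 0.045 Hz bandwidth); null-correlation bounds
in the tests use this effective n.

**CSD events.** On the hemisphere containing the origin only, a radially
propagating multiplicative flow transient (default: instantaneous rise to
gain 1.8 held ~90 s, transition to 0.7, linear recovery over 15 min at
3 fps; speed 0.7 px/frame, consistent with a few mm/min at mesoscopic
pixel sizes) and an attenuation of the *shared* homotopic component from
a floor of 0.15 back to 1 over 3000 frames. Attenuating only the shared
component is essential: scaling a pixel's whole series would leave its
correlation — and thus the index — unchanged. The schedule places block 1
in the suppressed window and block 3 after full restoration, reproducing
the transient connectivity loss qualitatively. The contralateral
hemisphere is bit-identical to a no-event run with the same seed.

**Vessel / occlusion fields.** Dark smoothed random-walk curves dilated
to random widths on a bright background, grown until the foreground
fraction is within 0.01 of target (the exact mask is the truth); and
near-black discs placed inside the window whose last radius is
binary-searched onto the target occluded fraction.

**Branched cells.** Disk soma plus `k` straight arms at evenly spaced,
randomly rotated angles, optionally bifurcating once (daughters at
+/-15 degrees), rasterized at the requested width on a background with a
smooth illumination gradient and noise to exercise the preprocessing.
True Sholl counts are `k` strictly between soma edge and arm tips, `2k`
beyond the bifurcation.

What these generators do *not* emulate: realistic vascular topology,
photon transport through skull, spatially varying speckle statistics,
heartbeat/respiration artifacts, or motion. Passing recovery tests
therefore demonstrates correctness of the computations under the stated
statistical model, not robustness to every artifact of in-vivo data.

## Microglia chain

`preprocess_microglia` applies, in order: Gaussian blur (sigma 0.5 px),
rolling-ball background subtraction (radius 50 px), Otsu binarization
(bright cells are foreground in fluorescence images), outlier removal
(replace a pixel by the median of its radius-2 disc when it deviates by
more than 50 on the 0-255 scale — on a binary image this despeckles
isolated flipped pixels), removal of connected components under 10 px,
and a radius-5 median filter. The rolling-ball step is implemented as
grayscale opening with a disc structuring element subtracted from the
image — a morphological variant of the classic paraboloid algorithm;
validation backgrounds are smooth gradients both variants remove.
Connected components use 8-connectivity throughout (the common
particle-analysis default), implemented as 4-connected labelling plus a
union-find merge of diagonally touching labels.

A practical scale constraint follows from the radius-5 median filter:
structures thinner than about 5 px are erased, so Sholl-grade imaging
needs the high-zoom pixel scale (~0.09 um/px, where a 1-um process spans
~12 px). At the counting scale (~0.9 um/px) somata survive the chain but
fine processes do not — which is exactly why counting works there (one
component per cell) while Sholl analysis uses the zoomed fields.

`sholl_profile` samples each 5-um ring at <= 1 px arc spacing and counts
maximal contiguous foreground runs, merging the run that wraps the
angular seam. The maximum radius defaults to the distance from the
center to the nearest border. Soma centers are supplied (or taken from
generator truth); automated soma detection is out of scope. The
brute-force oracle used in tests classifies every foreground pixel into a
1-px ring band and counts angular clusters; the two definitions coincide
for structures crossing rings transversally (the geometry Sholl analysis
is designed for) and are checked for exact agreement on random radial
arbors. Tangentially grazing blobs and ring-crossing arm *tips* are
genuinely ambiguous under discretization and are excluded from the
equivalence fixtures — not because the implementation is lenient there,
but because no unique correct count exists.

`fov_from_zoom` records the field-of-view bookkeeping (443 um base field,
177 um at 2.5x zoom) used to convert pixels to micrometers in configs.

## Problem sizes and numerical tolerances

The test and acceptance runs use deliberately compact problem sizes
chosen to exercise every code path with stable statistics: 32x32
bilateral movies of 1800 frames (the per-pair correlation estimate is
governed by the ~54 effective band-limited samples, not the pixel count,
and ~500 pairs x several seeds give the index mean a standard error well
below the 0.1 recovery tolerance), 160x160 speckle fields (~23k valid
windows), 256x256 vessel fields, and single-cell 640x640 Sholl fields at
0.0865 um/px. Recovery tolerances (0.1 clean / 0.15 with nuisance for the
index; 2 percentage points for area fractions) account for 8-bit
quantization, band-limited effective sample sizes, and histogram binning.
Zero-variance, constant-image, empty-mask and short-recording cases are
all handled by explicit guards with typed conditions rather than NaN
propagation.

## Known limitations

- Whole-image registration, motion correction and absolute flow
  calibration are out of scope.
- The homotopic reading of the mirror geometry is a deliberate
  interpretation (see above); a literal anterior-posterior reflection is
  not implemented.
- The occlusion "auto" method is a surrogate for manual counting and is
  validated only against the synthetic blob generator.
- 3-D Sholl on raw Z-stacks is not implemented; analysis operates on
  maximum projections.
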