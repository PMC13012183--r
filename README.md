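# mesowin

Analysis pipeline for longitudinal mesoscopic imaging through transparent
cranial windows in awake mice. Transparent-skull preparations are scored
and monitored with several optical readouts, and `mesowin` implements the
computational side of that workflow end to end:

- **LSCI flow mapping.** Laser speckle contrast `K = sigma / mu` over a
  sliding 7x7 window, converted to the inverse-correlation-time flow index
  `ICT = 1 / K^2`, with set averaging (15 raw frames per set, 9 flow-index
  images per stack) and relative-blood-flow (rBF) ROI traces.
- **Window transparency.** Brain-masked Otsu auto-thresholding of 530-nm
  reflectance (IOSI) images; the percentage of masked pixels occupied by
  (dark, hemoglobin-absorbing) vasculature is the transparency statistic,
  tracked longitudinally against a reference day. Occluded window area
  (drying artifacts/bubbles) is quantified on averaged LSCI images.
- **Interhemispheric homotopic connectivity.** The preprocessing chain
  downsample (512 -> 128 block means) -> linear detrend -> zero-phase
  Butterworth bandpass (0.035-0.08 Hz) -> global signal regression, then
  the Pearson correlation `r` of every pixel with its mirror pixel across
  the bregma-lambda midline, Fisher-transformed (`z = atanh r`) and
  averaged into the connectivity index. A block analysis (discard 500
  frames at 3 fps, then three 10-min blocks) quantifies the transient
  connectivity loss after a cortical spreading depolarization (CSD).
- **Microglia morphology.** The fixed binarization chain (Gaussian blur
  sigma 0.5, rolling-ball background subtraction radius 50 px, Otsu,
  outlier removal r = 2 / threshold = 50, minimum particle 10 px, median
  filter r = 5) followed by cell counting and Sholl analysis: process
  intersections with concentric 5-um rings around each soma.

Every stage comes with a seeded synthetic generator (dynamic speckle with
controllable correlation time, bilateral band-limited hemodynamics with
known mirror correlation, vessel and occlusion fields with exact masks,
propagating CSD-like flow transients, branched cells with analytic Sholl
profiles), so the whole pipeline is verifiable against ground truth
without any external data.

## Worked example

```r
library(mesowin)

# 1. Speckle contrast and flow index on a synthetic 15-frame set
p   <- speckle_sim_params(shape = c(15, 128, 128), tau_c_ms = 0.5,
                          exposure_ms = 5, seed = 1)
sim <- gen_speckle_stack(p)
K   <- compute_speckle_contrast(sim$stack, window_px = 7, mode = "per_frame")
ict <- contrast_to_ict(K)
# mean K = 0.325 (ensemble oracle 0.330), mean 1/K^2 = 9.49

# 2. Homotopic connectivity index of a bilateral movie with rho = 0.6
bp    <- bilateral_sim_params(shape = c(32, 32), n_frames = 1800,
                              rho = 0.6, seed = 1)
movie <- gen_bilateral_movie(bp)
pre   <- connectivity_preprocess(movie$movie)
idx   <- connectivity_index(homotopic_map(pre, movie$truth$midline))
# connectivity index = 0.689 over 1024 paired pixels (atanh(0.6) = 0.693)

# 3. Transparency statistic on a synthetic vessel field (20% true area)
v   <- gen_vessel_image(0.2, seed = 1)
rec <- vessel_area_fraction(v$image, day_label = "Day 0")
# vasculature = 19.6% of masked pixels (threshold 87.2)

# 4. Sholl profile of a synthetic 6-branched cell
mp <- morphology_sim_params(n_cells = 1, n_branches = 6,
                            branch_length_um = 24, soma_radius_um = 3,
                            branch_width_um = 1, pixel_size_um = 0.0865,
                            shape = c(640, 640), seed = 1)
cell <- gen_microglia_image(mp)
bw   <- preprocess_microglia(cell$image, pixel_size_um = mp$pixel_size_um)
sholl_profile(bw, cell$truth$centers[1, ], step_um = 5, max_radius_um = 20)
#   radius_um intersections
# 1         5             6
# 2        10             6
# 3        15             6
# 4        20             6
```

The interpretation: slower flow (longer correlation time relative to the
5-ms exposure) leaves higher contrast `K` and a lower flow index; the
connectivity index recovers `atanh(rho)` of the generating homotopic
correlation; the Otsu vessel fraction recovers the generator's area
fraction; and an unbranched 6-armed cell crosses every intermediate Sholl
ring exactly 6 times.

A thin command-line wrapper over the same functions ships in
`inst/cli/mesowin.R`:

```sh
Rscript inst/cli/mesowin.R simulate --kind vessel --out sim/ --seed 7
Rscript inst/cli/mesowin.R transparency --in sim/vessel.tif --out out/
```

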