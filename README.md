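# spiderwalk

Trajectory tracking and path analysis for nocturnal spider learning walks.

When a naive Namib Desert wandering spider first leaves a burrow in
unfamiliar terrain it walks away along a strikingly sinusoidal path,
apparently memorising the visual scenery that identifies its home — the
arachnid counterpart of the learning flights of bees and wasps. Establishing
that behaviour quantitatively requires a full measurement chain from dim
infrared video to statistics, and that chain is what this package
implements, for behavioural ecologists working with single-animal overhead
video:

* **Blob tracking** by batchwise temporal-mean subtraction: each 25-frame
  batch is cropped to a 300x300 px window centred on the animal, the
  per-pixel temporal mean is subtracted, |difference| is thresholded at 8
  (about 3% of the 8-bit range), spatiotemporal connected components are
  filtered by volume and cross-section eccentricity, and the per-frame
  centroid of the selected component becomes the track.
* **Planar calibration**: a normalized-DLT homography (optional radial
  distortion term) estimated from checkerboard corner correspondences — a
  1 m board with 9x9 squares of 11.11 cm — rectifies pixel tracks into
  burrow-centred ground centimetres.
* **Cleaning and smoothing**: an explicit jump rule (repeated >5 cm steps
  within <3 s) flags tracking mistakes; a constant-acceleration Kalman
  filter/RTS smoother (state x, y, x', y', x'', y'') denoises and bridges
  detection gaps.
* **Path-shape descriptors**: an orthogonal-regression travel axis with
  iterative refinement, axis crossings with hysteresis, per-cycle
  wavelengths `lambda_i` (alternate-crossing spacing) and amplitudes `A_i`
  (max |deviation| per half-cycle), excursion summaries (length, duration,
  mean speed with and without pauses), the distance-to-burrow departure
  rate, and a maximum-likelihood Rayleigh fit to frame-wise speeds
  (`sigma_hat = sqrt(sum(v^2)/2n)`; mean `sigma*sqrt(pi/2)`, variance
  `(4-pi)*sigma^2/2` — a distribution mean of 9.6 cm/s implies variance
  25.2).
* **Eye-field analysis**: the signed body-to-burrow alignment angle `alpha`
  per step, and which eyes' azimuthal visual fields (AME/ALE/PLE compass;
  the upwards-looking PME excluded) contain the burrow direction; circular
  means with expanded-percentile bootstrap confidence intervals.
* **PERMANOVA**: one-way permutational ANOVA on Bray–Curtis
  dissimilarities of fourth-root-transformed (wavelength, amplitude) rows,
  9951 permutations by default with the +1 Monte-Carlo correction, exact
  enumeration for small designs.
* **Synthetic scenes**: a ground-truth generator (sinusoidal departures,
  rendered vignetted noisy frame stacks, checkerboards under known
  homographies, Rayleigh speed samples) makes every stage testable without
  field recordings.

## Worked example

The demonstration pipeline simulates one departure (wavelength 50 cm,
amplitude 20 cm, 10 cm/s, 15 s at 25 Hz), renders it to a noisy vignetted
frame stack, tracks it, calibrates from a synthetic checkerboard with 0.2 px
corner noise, rectifies, flags, smooths, and measures:

```r
library(spiderwalk)
report <- run_pipeline(demo_config(outdir = "demo_out", seed = 1))
report
#> spiderwalk pipeline run
#>   output: demo_out
#>   stages: simulate -> track -> calibrate -> rectify -> clean -> smooth -> geometry -> eye_fields -> stats
#>   tracker RMSE vs truth: 1.768 px
#>   mean wavelength 50.08 cm, mean amplitude 19.88 cm
#>   PERMANOVA pseudo-F = 68.219, p = 0.0001005
```

The tracker recovers the blob to under 2 px (0.8 cm at the 2.5 px/cm demo
scale); the wavelength and amplitude estimates land within about half a
percent of the generative truth; and the PERMANOVA on a simulated
three-excursion descriptor table (wavelengths lengthening with experience)
rejects equality of excursion groups. `demo_out/` holds every intermediate:
`truth.csv`, `track_px.csv`, `calib.json`, `track_ground.csv`,
`track_smooth.csv`, `metrics.json`, `summary.csv`, `alpha.csv`,
`permanova.json`, `report.json`.

Single stages are plain functions — `gen_sinusoidal_path()`,
`track_video()`, `estimate_homography()`, `pixels_to_ground()`,
`flag_jumps()`, `kalman_smooth()`, `extract_sinusoid_metrics()`,
`fit_rayleigh()`, `alpha_series()`, `eyes_viewing()`,
`permanova_descriptors()` — and a thin command-line dispatcher is installed
at `inst/cli/spiderwalk` (`simulate-path`, `track`, `calibrate`, `rectify`,
`clean`, `smooth`, `analyze-path`, `eye-fields`, `permanova`, `run-all`).

## Vignette

`vignettes/learning-walk-pipeline.Rmd` documents the models and their
assumptions, the scene-generator defaults and what they emulate, the
numerical choices (axis refinement, crossing hysteresis, jerk-noise scaling,
expanded-percentile intervals), and known limitations.
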